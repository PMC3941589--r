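test_that("voltage state derives the mean-free potential and rejects non-finite input", {
  st <- voltage_state(u = -65, u_bar = -70, u_dot = 0.5)
  expect_equal(st$u_hat, 5)
  expect_error(voltage_state(NaN, -70, 0), "finite")
  expect_error(gradient_params(gamma = 0), "gamma")
  expect_error(gradient_params(sigma2 = -1), "sigma2")
})

test_that("time-averaged Wiener moments match their closed forms", {
  # all sources off -> both moments vanish
  silent <- voltage_state(0, 0, 0)
  p0 <- gradient_params(sigma2 = 0, delta = 0.5)
  expect_identical(wiener_moment(2, silent, p0), 0)
  expect_identical(wiener_moment(3, silent, p0), 0)

  # second moment, direct evaluation of the closed form
  st <- voltage_state(2, 0, 1)
  p <- gradient_params(sigma2 = 0.036, delta = 0.1)
  expect_equal(wiener_moment(2, st, p), 4.2051333, tolerance = 1e-7)

  expect_error(wiener_moment(4, st, p), "unsupported")
})

test_that("closed-form moments agree with the Monte-Carlo Wiener oracle", {
  cases <- list(
    list(u_hat = 2, u_dot = 1, sigma2 = 0.036, delta = 0.1),
    list(u_hat = 1, u_dot = 0.5, sigma2 = 0.036, delta = 0.2),
    list(u_hat = -1.5, u_dot = 2, sigma2 = 0.1, delta = 0.15)
  )
  for (cs in cases) {
    st <- voltage_state(cs$u_hat, 0, cs$u_dot)
    p <- gradient_params(sigma2 = cs$sigma2, delta = cs$delta)
    mc <- monte_carlo_moments(st, p, n_paths = 1e5, seed = 99)
    expect_lt(abs(mc$m2 - wiener_moment(2, st, p)), 3 * mc$se2)
    expect_lt(abs(mc$m3 - wiener_moment(3, st, p)), 3 * mc$se3)
  }
})

test_that("Monte-Carlo oracle is exact for pure drift and reproducible under a seed", {
  st <- voltage_state(1, 0, 2)
  p <- gradient_params(sigma2 = 0, delta = 0.2)
  mc <- monte_carlo_moments(st, p, n_paths = 1000, seed = 1, n_steps = 400)
  # deterministic path: time average is a quadrature of a polynomial
  expect_equal(mc$m2, wiener_moment(2, st, p), tolerance = 1e-5)
  expect_identical(mc$se2, 0)

  p2 <- gradient_params(sigma2 = 0.036, delta = 0.1)
  a <- monte_carlo_moments(st, p2, n_paths = 2000, seed = 7)
  b <- monte_carlo_moments(st, p2, n_paths = 2000, seed = 7)
  expect_identical(a, b)
})

test_that("sample skewness reduces to the point-mass limit and is odd in u_hat", {
  p_small <- gradient_params(sigma2 = 0, delta = 1e-9)
  expect_equal(sample_skewness(voltage_state(1, 0, 0), p_small), 1,
               tolerance = 1e-6)
  expect_equal(sample_skewness(voltage_state(-1, 0, 0), p_small), -1,
               tolerance = 1e-6)
  expect_error(sample_skewness(voltage_state(0, 0, 0),
                               gradient_params(sigma2 = 0)), "undefined")

  # generic state: ratio of the two closed forms
  st <- voltage_state(2, 0, 1)
  p <- gradient_params(sigma2 = 0.036, delta = 0.1)
  expect_equal(sample_skewness(st, p),
               wiener_moment(3, st, p) / wiener_moment(2, st, p)^1.5)
})

test_that("regularized gradients evaluate to their pinned closed-form values", {
  tiny <- 1e-9   # stands in for gamma = 0 in the unregularized limit
  st <- voltage_state(5, 0, 1)
  expect_equal(skewness_gradient(st, gradient_params(gamma = tiny)),
               9.856e-3, tolerance = 1e-6)
  expect_equal(kurtosis_gradient(st, gradient_params(gamma = tiny)),
               2.637867e-2, tolerance = 1e-6)

  # u_hat -> 0 limit is forced to zero by the |u_hat|^3 factor
  expect_equal(skewness_gradient(voltage_state(1e-12, 0, 5),
                                 gradient_params()), 0, tolerance = 1e-30)
})

test_that("the sign of the noise-driven branch follows the moment parity", {
  p <- gradient_params(measure = "kurtosis")
  # skewness (odd moment): the -2 sigma^2 |u_hat|^3 numerator is negative
  # for either sign of u_hat
  expect_lt(skewness_gradient(voltage_state(5, 0, 0), p), 0)
  expect_lt(skewness_gradient(voltage_state(-5, 0, 0), p), 0)
  # kurtosis (even moment): the -1.5 sigma^2 u_hat^5 numerator flips with
  # the sign of u_hat, so the u_hat < 0 branch does not depress
  expect_lt(kurtosis_gradient(voltage_state(5, 0, 0), p), 0)
  expect_gt(kurtosis_gradient(voltage_state(-5, 0, 0), p), 0)
})

test_that("gradient matches the finite difference of the sample skewness (order delta^2)", {
  set.seed(42)
  n_checked <- 0
  for (i in 1:20) {
    u_hat <- sample(c(-1, 1), 1) * runif(1, 2, 30)
    u_dot <- runif(1, -3, 3)
    sigma2 <- runif(1, 0, 0.1)
    fd <- fd_skew_gradient(u_hat, u_dot, sigma2, delta = 1e-3)
    analytic <- skewness_gradient(voltage_state(u_hat, 0, u_dot),
                                  gradient_params(sigma2 = sigma2,
                                                  gamma = 1e-9))
    expect_equal(fd / 1e-6, analytic, tolerance = 0.01)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 20)
})

test_that("the numerical skewness derivative scales as delta^2", {
  # the delta^0 terms are u_dot-independent and the delta^1 terms cancel,
  # so the leading dependence is quadratic in the window length
  deltas <- 10^seq(-3, -1, length.out = 7)
  fd <- vapply(deltas, function(d) {
    abs(fd_skew_gradient(u_hat = 5, u_dot = 1, sigma2 = 0.036, delta = d))
  }, numeric(1))
  slope <- coef(lm(log(fd) ~ log(deltas)))[2]
  expect_equal(unname(slope), 2.0, tolerance = 0.05)
})

test_that("gradient sign structure switches exactly at u_hat * u_dot = 2 sigma^2", {
  p <- gradient_params()
  u_dot <- 0.3
  u_star <- 2 * p$sigma2 / u_dot
  at <- skewness_gradient(voltage_state(u_star, 0, u_dot), p)
  expect_lt(abs(at), 1e-15)
  expect_lt(skewness_gradient(voltage_state(u_star * 0.9, 0, u_dot), p), 0)
  expect_gt(skewness_gradient(voltage_state(u_star * 1.1, 0, u_dot), p), 0)
})

test_that("mean-potential filter is the exact exponential update", {
  # fixed point
  expect_identical(update_mean_potential(-70, -70, 0.1, 30000), -70)
  # constant input held for one time constant decays the error by e^-1
  u_bar <- -70
  for (i in 1:300000) u_bar <- update_mean_potential(u_bar, -60, 0.1, 30000)
  expect_equal(u_bar, -60 + (-70 + 60) * exp(-1), tolerance = 1e-9)
  expect_error(update_mean_potential(-70, -60, -1, 30), "positive")
})
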