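test_that("conductance waveform vanishes at onset and is unit-normalized", {
  tg <- seq(0, 400, by = 0.01)
  for (kin in list(ampa_kinetics(), nmda_kinetics())) {
    expect_identical(conductance_waveform(0, kin), 0)
    pk <- max(conductance_waveform(tg, kin))
    expect_gte(pk, 0.98)
    expect_lte(pk, 1.02)
  }
  expect_error(conductance_waveform(-1, ampa_kinetics()), "non-negative")
  expect_error(receptor_kinetics(3, 2, 8, 0.5, 1), "tau_r")
})

test_that("AMPA waveform matches the triple-exponential closed form at t = 2 ms", {
  expect_equal(conductance_waveform(2, ampa_kinetics()),
               2.00 * (0.8 * exp(-1) + 0.2 * exp(-0.25) - exp(-2 / 0.55)),
               tolerance = 1e-12)
  expect_equal(conductance_waveform(2, ampa_kinetics()), 0.847,
               tolerance = 1e-3)
})

test_that("magnesium unblock is the Jahr-Stevens sigmoid", {
  mg <- mg_block_params()
  expect_equal(mg_unblock(0, mg), 1 / (1 + 1 / 3.57), tolerance = 1e-12)
  expect_equal(mg_unblock(0, mg), 0.781, tolerance = 1e-3)
  expect_equal(mg_unblock(-70, mg), 0.0445, tolerance = 1e-3)
  # strictly increasing and bounded in (0, 1)
  u <- seq(-120, 80, by = 1)
  f <- mg_unblock(u, mg)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
  expect_gt(mg_unblock(1e4, mg), 1 - 1e-12)
  expect_error(mg_block_params(alpha = -1), "positive")
})

test_that("synaptic currents respect reversal, composition and causality", {
  syn <- synapse(w_ampa = 200, w_nmda = 500, presyn_times = c(10, 30))
  # reversal potential
  expect_equal(synaptic_current(15, 0, syn)$total, 0)
  # before the first presynaptic spike there are no open channels
  expect_identical(synaptic_current(5, -70, syn)$total, 0)
  # AMPA-free synapse: total equals the NMDA component
  syn0 <- synapse(w_ampa = 0, w_nmda = 500, presyn_times = 10)
  cur <- synaptic_current(20, -60, syn0)
  expect_identical(cur$ampa, 0)
  expect_equal(cur$total, cur$nmda)
  expect_gt(cur$nmda, 0)
})

test_that("synapse validates the channel-count factor decomposition", {
  expect_silent(synapse(w_nmda = 500,
                        n_channels = list(ampa = 0, nmda = 100),
                        g_single = list(ampa = 0, nmda = 5)))
  expect_error(synapse(w_nmda = 500,
                       n_channels = list(ampa = 0, nmda = 100),
                       g_single = list(ampa = 0, nmda = 4)),
               "inconsistent")
})

test_that("weight derivative is the three-factor rule, linear in the current", {
  st <- voltage_state(5, 0, 1)
  p <- gradient_params()   # eta 1.5 s, gamma 10, sigma2 0.036
  dw <- weight_derivative(10, st, p, capacitance = 10)
  expect_equal(dw, 1500 * (10 / 10) * 0.25 * (5 - 0.072) * 125 / (5^6 + 1e6),
               tolerance = 1e-12)
  expect_equal(dw, 0.2274461, tolerance = 1e-6)
  # no presynaptic current, no change
  expect_identical(weight_derivative(0, st, p, 10), 0)
  # exact linearity in I_R (differential-Hebbian structure)
  expect_equal(weight_derivative(7, st, p, 10) * 3,
               weight_derivative(21, st, p, 10))
  # depression branch: u_hat > 0 but u_hat * u_dot < 2 sigma^2
  st_dep <- voltage_state(2, 0, 0.01)
  expect_lt(weight_derivative(5, st_dep, p, 10), 0)
})

test_that("channel-number/conductance factor dynamics conserve the coupled ratio", {
  # Omega = 0 is a fixed point
  r0 <- step_factors(100, 5, omega = 0, dt = 10, eta_g = 0.1, eta_n = 0.4)
  expect_equal(r0$n, 100)
  expect_equal(r0$g, 5)

  # g/N = sqrt(eta_g/eta_n) is conserved and the weight is multiplicative
  eta_g <- 0.02; eta_n <- 0.08; omega <- 0.5
  n0 <- 10; g0 <- n0 * sqrt(eta_g / eta_n)
  r <- step_factors(n0, g0, omega, dt = 4, eta_g = eta_g, eta_n = eta_n,
                    n_steps = 400)
  expect_lt(r$ratio_drift, 1e-9)
  w_expect <- n0 * g0 * exp(2 * sqrt(eta_g * eta_n) * omega * 4)
  expect_equal(r$w, w_expect, tolerance = 1e-8)

  # eta_g = 0: additive limit, dw/dt = eta_n g^2 Omega independent of w
  ra <- step_factors(10, 3, omega = 0.2, dt = 5, eta_g = 0, eta_n = 0.1)
  expect_equal(ra$w, 10 * 3 + 0.1 * 3^2 * 0.2 * 5, tolerance = 1e-10)

  expect_error(step_factors(-1, 1, 0, 1, 0.1, 0.1), "positive")
})
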