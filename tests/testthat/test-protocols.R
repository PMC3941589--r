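test_that("poisson_train is a seeded homogeneous Poisson process", {
  expect_identical(poisson_train(0, 10, 1), numeric())
  expect_identical(poisson_train(3, 50, 7), poisson_train(3, 50, 7))
  expect_false(identical(poisson_train(3, 50, 7), poisson_train(3, 50, 8)))
  expect_error(poisson_train(-1, 1, 1), ">= 0")

  counts <- numeric(200)
  cvs <- numeric(200)
  for (s in 1:200) {
    tr <- poisson_train(3, 100, s)
    counts[s] <- length(tr)
    iv <- diff(tr)
    cvs[s] <- sd(iv) / mean(iv)
  }
  expect_equal(mean(counts), 300, tolerance = 0.05)
  expect_equal(mean(cvs), 1, tolerance = 0.05)
  # generating a train does not disturb the global RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(poisson_train(3, 10, 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("pairing schedules reject delays longer than the pairing period", {
  expect_error(pairing_schedule(-150, 10, 10), "period")
  s <- pairing_schedule(-10, 100, 20)
  expect_identical(s$n_pairs, 100L)
})

test_that("zero pairings leave the synapse exactly unchanged", {
  r <- run_stdp_pairing(delay = 10, n_pairs = 0)
  expect_identical(r$relative_change, 0)
  expect_identical(r$w_before, r$w_after)
})

test_that("pairing runs are bit-reproducible", {
  a <- run_stdp_pairing(delay = -10)
  b <- run_stdp_pairing(delay = -10)
  expect_identical(a$relative_change, b$relative_change)
})

test_that("pre-post pairing potentiates and post-pre pairing depresses", {
  ltp <- run_stdp_pairing(delay = 10)
  ltd <- run_stdp_pairing(delay = -10)
  expect_gt(ltp$relative_change, 0.05)
  expect_lt(ltd$relative_change, -0.05)
})

test_that("priming narrows the depression window of the delay sweep", {
  delays <- c(-25, -20, -15, -10, -5)
  ctrl <- run_delay_sweep(delays)
  prim <- run_delay_sweep(delays, priming = TRUE)
  expect_lt(ltd_window_width(prim, interpolate = TRUE),
            ltd_window_width(ctrl, interpolate = TRUE))
  # and the window edge itself: depression still present at -15 ms in the
  # control branch, (nearly) gone after priming
  expect_lt(ctrl$relative_change[ctrl$delay == -15], -0.05)
  expect_gt(prim$relative_change[prim$delay == -15],
            ctrl$relative_change[ctrl$delay == -15])
})

test_that("the LTD window measure reads the sweep as documented", {
  sweep <- data.frame(delay = c(-30, -20, -10, 10),
                      relative_change = c(0.004, -0.02, -0.4, 0.5))
  expect_equal(ltd_window_width(sweep), 20)
  expect_equal(ltd_window_width(sweep, threshold = 0.1), 10)
  # interpolated edge: crossing of -0.01 between -30 and -20
  expect_equal(ltd_window_width(sweep, interpolate = TRUE),
               20 + 10 * (0.02 - 0.01) / (0.02 + 0.004))
  expect_equal(ltd_window_width(data.frame(delay = -10, relative_change = 0.2)), 0)
})

test_that("sign_crossover interpolates the first sign change", {
  expect_equal(sign_crossover(c(10, 20, 30), c(-1, -0.5, 0.5)), 25)
  expect_true(is.na(sign_crossover(c(1, 2), c(-1, -2))))
})

test_that("at 50 Hz the +10 ms and -10 ms pairings become equivalent and potentiate", {
  a <- run_stdp_pairing(delay = 10, n_pairs = 100, rep_frequency = 50,
                        distance = 150, w_ampa = 0)
  b <- run_stdp_pairing(delay = -10, n_pairs = 100, rep_frequency = 50,
                        distance = 150, w_ampa = 0)
  expect_gt(a$relative_change, 0)
  expect_gt(b$relative_change, 0)
  expect_lt(abs(a$relative_change - b$relative_change),
            0.5 * abs(a$relative_change) + 0.05)
})

test_that("post-before-pre pairing at 10 Hz depresses the NMDA-only synapse", {
  r <- run_stdp_pairing(delay = -10, n_pairs = 100, rep_frequency = 10,
                        distance = 150, w_ampa = 0)
  expect_lt(r$relative_change, -0.1)
})

test_that("without presynaptic input the rate protocol changes nothing", {
  r <- run_rate_protocol(post_rate = 5, pre_rate = 0, duration = 5, seed = 3)
  expect_identical(r$relative_change, 0)
})

test_that("small plastic changes scale linearly with the learning rate", {
  weak <- plasticity_config(c_eff = 150)
  weak2 <- plasticity_config(params = gradient_params(eta = 3.0), c_eff = 150)
  a <- run_stdp_pairing(delay = -10, plast = weak)$relative_change
  b <- run_stdp_pairing(delay = -10, plast = weak2)$relative_change
  expect_equal(b / a, 2, tolerance = 0.05)
})

test_that("voltage clamp at rest induces nothing; depolarization opens a depression window", {
  rest <- run_voltage_clamp(-70)
  expect_lt(abs(rest$relative_change), 0.005)
  mid <- run_voltage_clamp(-40)
  expect_lt(mid$relative_change, -0.05)
  # toward strong depolarization the depression recedes again
  strong <- run_voltage_clamp(-10)
  expect_gt(strong$relative_change, mid$relative_change)
})

test_that("scaling sigma with synaptic strength shifts the voltage-clamp window", {
  # depressed synapse (smaller sigma): less depression at intermediate
  # commands; potentiated synapse (larger sigma): more
  ctrl <- run_voltage_clamp(-30)$relative_change
  dep <- run_voltage_clamp(-30, w_scale = 0.5,
                           sigma_scaling = TRUE)$relative_change
  pot <- run_voltage_clamp(-30, w_scale = 2,
                           sigma_scaling = TRUE)$relative_change
  expect_gt(dep, ctrl)
  expect_lt(pot, ctrl)
})

test_that("the population protocol starts from an unskewed delta peak", {
  pop <- run_population(n_syn = 10, duration = 0, n_trials = 1, seed = 1)
  st <- population_strengths(pop, 0)[[1]]
  expect_true(all(st == st[1]))
  expect_equal(st[1], 0.16, tolerance = 1e-3)
})

test_that("population runs are reproducible and carry per-checkpoint strengths", {
  a <- run_population(n_syn = 8, duration = 5, n_trials = 1, seed = 4,
                      checkpoints = 5)
  b <- run_population(n_syn = 8, duration = 5, n_trials = 1, seed = 4,
                      checkpoints = 5)
  expect_identical(a$trials[[1]]$weights, b$trials[[1]]$weights)
  expect_identical(dim(a$trials[[1]]$strengths), c(1L, 8L))
})

test_that("the weight calibration hits the requested somatic EPSP", {
  w <- calibrate_weight(0.16)
  expect_equal(measure_epsp(cable_config(), soma_spec(), 200, 0, w), 0.16,
               tolerance = 1e-3)
})
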