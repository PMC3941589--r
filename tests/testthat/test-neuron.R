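test_that("an unstimulated neuron stays at rest", {
  m <- build_neuron(fast_cable())
  r <- simulate_neuron(m, 1000, record_nodes = "all", record_dt = 100)
  expect_lt(max(abs(r$v - (-70))), 1e-9)
})

test_that("steady somatic clamp reproduces the analytic sealed-end profile", {
  cab <- cable_config()
  m <- set_voltage_clamp(build_neuron(cab), clamp_spec(-30))
  r <- simulate_neuron(m, 500, record_nodes = "all", record_dt = 100)
  prof <- r$v[nrow(r$v), -1] - cab$resting_potential
  analytic <- cable_steady_profile(cab, m$centers, v0 = 40)
  expect_lt(max(abs(prof - analytic) / analytic), 0.02)
  # the clamped node itself holds the command exactly at every sample
  expect_true(all(r$v[-1, 1] == -30))
})

test_that("synapse placement maps deterministically and rejects off-cable distances", {
  m <- build_neuron()
  i <- distance_to_compartment(m, 200)
  expect_identical(i, distance_to_compartment(m, 200))
  expect_equal(m$centers[i], 200, tolerance = m$dx)
  expect_error(distance_to_compartment(m, 900), "beyond")
  expect_error(attach_synapse(m, synapse(distance = 1e4)), "beyond")
})

test_that("a clamp at rest leaves spine heads motionless", {
  m <- build_neuron()
  m <- attach_synapse(m, synapse(w_nmda = 500, distance = 300))
  m <- set_voltage_clamp(m, clamp_spec(-70))
  r <- simulate_neuron(m, 200, record_dt = 1)
  expect_lt(max(abs(r$head_udot)), 1e-9)
  expect_lt(max(abs(r$head_u - (-70))), 1e-9)
})

test_that("the backpropagating AP attenuates and broadens with distance", {
  m <- schedule_ap(build_neuron(), 20)
  r <- simulate_neuron(m, 150, record_nodes = "all", record_dt = 0.1)
  stats <- lapply(c(200, 400, 600), function(d) {
    j <- distance_to_compartment(m, d) + 1
    v <- r$v[, j] + 70
    pk <- max(v)
    list(peak = pk, hw = diff(range(r$times[v >= pk / 2])))
  })
  peaks <- vapply(stats, `[[`, numeric(1), "peak")
  hws <- vapply(stats, `[[`, numeric(1), "hw")
  expect_true(all(diff(peaks) < 0))
  expect_true(all(diff(hws) > 0))
})

test_that("with inputs off the deviation from rest decays monotonically", {
  m <- build_neuron()
  m$injections <- rbind(m$injections, c(t0 = 0, dur = 5, amp = 500))
  r <- simulate_neuron(m, 400, record_nodes = "all", record_dt = 5)
  dev <- rowSums(abs(r$v + 70))
  tail_dev <- dev[r$times > 10]
  expect_true(all(diff(tail_dev) < 0))
})

test_that("a clamp step settles to the analytic attenuation of the command offset", {
  cab <- cable_config()
  m <- build_neuron(cab)
  m <- attach_synapse(m, synapse(w_nmda = 0, w_ampa = 0, distance = 700))
  m <- set_voltage_clamp(m, clamp_spec(-30))
  r <- simulate_neuron(m, 600, record_nodes = distance_to_compartment(m, 700),
                       record_dt = 100)
  offset <- r$v[nrow(r$v), 1] + 70
  expect_equal(offset, cable_steady_profile(cab, 700, 40), tolerance = 0.02)
})

test_that("halving the integration step barely changes the recorded traces", {
  run_at <- function(dt) {
    m <- build_neuron(cable_config(dt = dt))
    m <- attach_synapse(m, synapse(w_ampa = 200, w_nmda = 500,
                                   distance = 200, presyn_times = 30))
    m <- schedule_ap(m, 40)
    simulate_neuron(m, 150, record_nodes = 0, record_dt = 1)
  }
  a <- run_at(0.1)
  b <- run_at(0.05)
  amp <- max(abs(a$v + 70))
  expect_lt(max(abs(a$v - b$v)) / amp, 0.005)
})

test_that("one eliciting pulse triggers exactly one stereotyped AP, repeatably", {
  m <- build_neuron()
  m <- elicit_postsynaptic_spike(m, c(50, 150))
  r <- simulate_neuron(m, 300, record_nodes = 5, record_dt = 0.1)
  expect_identical(length(r$spikes), 2L)
  # the two bAPs are identical waveforms at the same recording site
  # (time invariance of the passive cable)
  win <- function(t0) r$v[r$times >= t0 & r$times < t0 + 60, 1] + 70
  w1 <- win(r$spikes[1]); w2 <- win(r$spikes[2])
  expect_lt(max(abs(w1 - w2)) / max(w1), 0.02)
})

test_that("numerical blow-up raises an integration-failure error", {
  m <- build_neuron()
  m$injections <- rbind(m$injections, c(t0 = 0, dur = 50, amp = 1e7))
  expect_error(simulate_neuron(m, 100), "integration failure")
})
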