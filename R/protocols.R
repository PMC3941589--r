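#' Seeded homogeneous Poisson spike train
#'
#' @param rate Firing rate (Hz), >= 0.
#' @param duration Train duration (s).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return Sorted spike times (ms).
#' @export
poisson_train <- function(rate, duration, seed) {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (rate == 0) return(numeric())
  withr::with_seed(seed, {
    # draw intervals in blocks until the horizon is passed
    t_ms <- numeric()
    last <- 0
    horizon <- duration * 1000
    repeat {
      n <- max(100, ceiling(rate * duration * 1.5))
      iv <- stats::rexp(n, rate / 1000)
      t_ms <- c(t_ms, last + cumsum(iv))
      last <- t_ms[length(t_ms)]
      if (last > horizon) break
    }
    t_ms[t_ms <= horizon]
  })
}

#' Pairing schedule for STDP protocols
#'
#' @param delay Post-minus-pre delay (ms); negative means post before pre.
#' @param n_pairs Number of pairings.
#' @param rep_frequency Repetition frequency (Hz).
#' @export
pairing_schedule <- function(delay, n_pairs, rep_frequency) {
  if (rep_frequency <= 0) stop("rep_frequency must be > 0", call. = FALSE)
  if (abs(delay) >= 1000 / rep_frequency) {
    stop("|delay| must be smaller than the pairing period", call. = FALSE)
  }
  structure(list(delay = delay, n_pairs = as.integer(n_pairs),
                 rep_frequency = rep_frequency),
            class = "pairing_schedule")
}

# internal: single-synapse model builder
single_synapse_model <- function(cable, soma, distance, w_ampa, w_nmda,
                                 presyn_times = numeric(), sigma2_scale = 1) {
  m <- build_neuron(cable, soma)
  attach_synapse(m, synapse(w_ampa = w_ampa, w_nmda = w_nmda,
                            distance = distance, presyn_times = presyn_times,
                            sigma2_scale = sigma2_scale))
}

#' Measure synaptic strength by a somatic EPSP probe
#'
#' One presynaptic test pulse delivered from rest with plasticity frozen and
#' spiking disabled; the strength is the EPSP peak amplitude at the soma.
#'
#' @param cable,soma Neuron configuration.
#' @param distance Synapse location (um).
#' @param w_ampa,w_nmda Weights to probe (pS).
#' @param probe_ms Probe window (ms).
#' @return EPSP peak amplitude (mV).
#' @export
measure_epsp <- function(cable, soma, distance, w_ampa, w_nmda,
                         probe_ms = 200) {
  m <- single_synapse_model(cable, soma, distance, w_ampa, w_nmda,
                            presyn_times = 1)
  r <- simulate_neuron(m, probe_ms, plasticity = NULL, record_dt = cable$dt,
                       record_nodes = 0, syn_traces = FALSE)
  epsp_peak(r$v[, 1], baseline = cable$resting_potential)
}

# internal: package a protocol run
protocol_result <- function(protocol_name, config, epsp_before, epsp_after,
                            w_before, w_after, seed = NA_integer_,
                            trajectory = NULL, extra = list()) {
  rel <- (epsp_after - epsp_before) / epsp_before
  structure(
    c(list(protocol_name = protocol_name, config = config,
           epsp_before = epsp_before, epsp_after = epsp_after,
           relative_change = rel, w_before = w_before, w_after = w_after,
           seed = seed, trajectory = trajectory), extra),
    class = "protocol_result"
  )
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result:%s> EPSP %.4f -> %.4f mV (%+.1f%%)\n",
              x$protocol_name, x$epsp_before, x$epsp_after,
              100 * x$relative_change))
  invisible(x)
}

#' STDP pairing protocol
#'
#' Pairs presynaptic spikes with elicited postsynaptic action potentials at a
#' fixed delay (post minus pre) and repetition frequency, integrates the
#' plasticity rule, and reports the relative change of the somatic EPSP peak
#' (probes run with plasticity frozen). Default synapse: 200 um,
#' w_AMPA = 200 pS, w_NMDA = 500 pS, 7 pairings at 1 Hz.
#'
#' @param schedule A [pairing_schedule()] (or `delay` plus defaults).
#' @param delay,n_pairs,rep_frequency Shortcut arguments used when
#'   `schedule` is `NULL`.
#' @param distance Synapse location (um).
#' @param w_ampa,w_nmda Initial weights (pS).
#' @param priming If `TRUE`, a 100 Hz / 3 s burst of somatic APs precedes
#'   the pairing (metaplasticity variant).
#' @param cable,soma,plast Model configuration.
#' @return A `protocol_result`.
#' @export
run_stdp_pairing <- function(schedule = NULL, delay = 10, n_pairs = 7,
                             rep_frequency = 1, distance = 200,
                             w_ampa = 200, w_nmda = 500, priming = FALSE,
                             cable = cable_config(), soma = soma_spec(),
                             plast = plasticity_config()) {
  if (is.null(schedule)) {
    schedule <- pairing_schedule(delay, n_pairs, rep_frequency)
  }
  ep0 <- measure_epsp(cable, soma, distance, w_ampa, w_nmda)
  if (schedule$n_pairs == 0) {
    return(protocol_result("stdp_pairing", schedule, ep0, ep0,
                           c(w_ampa, w_nmda), c(w_ampa, w_nmda)))
  }
  t0 <- if (priming) 3300 else 100
  period <- 1000 / schedule$rep_frequency
  base <- t0 + (seq_len(schedule$n_pairs) - 1) * period
  pre <- base + max(0, -schedule$delay)
  post <- base + max(0, schedule$delay)
  m <- single_synapse_model(cable, soma, distance, w_ampa, w_nmda,
                            presyn_times = pre)
  if (priming) m <- schedule_ap(m, seq(100, 3090, by = 10))
  m <- elicit_postsynaptic_spike(m, post)
  dur <- max(pre[length(pre)], post[length(post)]) + 300
  r <- simulate_neuron(m, dur, plasticity = plast, record_dt = dur,
                       record_nodes = 0, syn_traces = FALSE,
                       weight_dt = period)
  wf <- c(r$w_ampa_final[1], r$w_nmda_final[1])
  ep1 <- measure_epsp(cable, soma, distance, wf[1], wf[2])
  protocol_result("stdp_pairing",
                  c(unclass(schedule), list(distance = distance,
                                            priming = priming)),
                  ep0, ep1, c(w_ampa, w_nmda), wf,
                  trajectory = list(times = r$w_times, w_ampa = r$w_ampa[, 1],
                                    w_nmda = r$w_nmda[, 1]))
}

#' STDP delay sweep
#'
#' Runs [run_stdp_pairing()] over a vector of delays (control or primed) and
#' returns one row per delay.
#'
#' @param delays Delays (ms), post minus pre.
#' @param ... Passed to [run_stdp_pairing()].
#' @return Data frame with `delay`, `epsp_before`, `epsp_after`,
#'   `relative_change`.
#' @export
run_delay_sweep <- function(delays, ...) {
  rows <- lapply(delays, function(d) {
    r <- run_stdp_pairing(delay = d, ...)
    data.frame(delay = d, epsp_before = r$epsp_before,
               epsp_after = r$epsp_after,
               relative_change = r$relative_change)
  })
  do.call(rbind, rows)
}

#' Width of the depression window of an STDP delay sweep
#'
#' Operational definition of the LTD window: the largest |negative delay|
#' whose relative EPSP change is below `-threshold` (default 1%, the
#' smallest change resolvable in the induction experiments emulated here;
#' beyond the backpropagating-AP window the rule still produces a
#' vanishingly small noise-driven depression, so a strict sign test would be
#' degenerate).
#'
#' @param sweep Data frame from [run_delay_sweep()] (negative delays).
#' @param threshold Minimal depression magnitude counted as LTD.
#' @param interpolate If `TRUE`, the window edge is the linear interpolation
#'   of the `-threshold` crossing between the bracketing grid delays,
#'   instead of the largest probed delay still below it.
#' @return Window width (ms, positive).
#' @export
ltd_window_width <- function(sweep, threshold = 0.01, interpolate = FALSE) {
  neg <- sweep[sweep$delay < 0, ]
  neg <- neg[order(neg$delay), ]
  dep <- neg$delay[neg$relative_change < -threshold]
  if (length(dep) == 0) return(0)
  edge <- max(abs(dep))
  if (!interpolate) return(edge)
  i <- match(-edge, neg$delay)
  if (i == 1) return(edge)
  y1 <- neg$relative_change[i]        # below -threshold
  y0 <- neg$relative_change[i - 1]    # at the longer delay, above it
  edge + (abs(neg$delay[i - 1]) - edge) * (-threshold - y1) / (y0 - y1)
}

#' STDP repetition-frequency sweep
#'
#' 100 pairings at fixed delays as a function of the repetition frequency,
#' for a proximal synapse (150 um) containing only NMDA receptors.
#'
#' @param delays Delays (ms).
#' @param frequencies Repetition frequencies (Hz).
#' @param n_pairs Pairings per point.
#' @param distance Synapse location (um).
#' @param w_ampa,w_nmda Weights (pS).
#' @param cable,soma,plast Model configuration.
#' @return Data frame with one row per (delay, frequency).
#' @export
run_frequency_sweep <- function(delays = c(10, -10),
                                frequencies = c(0.1, 5, 10, 20, 30, 40, 50),
                                n_pairs = 100, distance = 150,
                                w_ampa = 0, w_nmda = 500,
                                cable = cable_config(), soma = soma_spec(),
                                plast = plasticity_config()) {
  grid <- expand.grid(delay = delays, frequency = frequencies)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- run_stdp_pairing(delay = grid$delay[i], n_pairs = n_pairs,
                          rep_frequency = grid$frequency[i],
                          distance = distance, w_ampa = w_ampa,
                          w_nmda = w_nmda, cable = cable, soma = soma,
                          plast = plast)
    data.frame(delay = grid$delay[i], frequency = grid$frequency[i],
               epsp_before = r$epsp_before, epsp_after = r$epsp_after,
               relative_change = r$relative_change)
  })
  do.call(rbind, rows)
}

#' Interpolated zero crossing of a response curve
#'
#' Linear interpolation between the bracketing grid points of the first sign
#' change of `y` along increasing `x` (e.g. the LTD-to-LTP crossover
#' frequency of the post-before-pre pairing curve).
#'
#' @param x,y Numeric vectors.
#' @return Interpolated `x` at the sign change, or `NA` if none.
#' @export
sign_crossover <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  s <- sign(y)
  i <- which(s[-length(s)] != s[-1] & s[-length(s)] != 0)
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  x[i] + (x[i + 1] - x[i]) * (0 - y[i]) / (y[i + 1] - y[i])
}

# internal: mean spine-head elevation per unit event rate (mV*ms per event),
# used to initialize u_bar for a given activity history
event_voltage_integral <- function(cable, soma, distance, w_ampa, w_nmda,
                                   type = c("bap", "epsp")) {
  type <- match.arg(type)
  m <- single_synapse_model(cable, soma, distance, w_ampa, w_nmda,
                            presyn_times = if (type == "epsp") 20 else numeric())
  if (type == "bap") m <- schedule_ap(m, 20)
  r <- simulate_neuron(m, 400, plasticity = NULL, record_dt = cable$dt,
                       record_nodes = 0, syn_traces = TRUE)
  sum(r$head_u - cable$resting_potential) * cable$dt
}

#' Rate-dependent (BCM) conditioning protocol
#'
#' Independent pre- and postsynaptic Poisson trains; the presynaptic rate is
#' fixed (default 10 Hz) and plasticity is probed as a function of the
#' postsynaptic conditioning rate. The running average `u_bar` starts at the
#' value corresponding to a 10 Hz postsynaptic activity history; with
#' `priming = TRUE` a 100 Hz / 3 s somatic burst precedes the conditioning.
#'
#' @param post_rate Postsynaptic conditioning rate (Hz).
#' @param pre_rate Presynaptic rate (Hz).
#' @param duration Conditioning duration (s).
#' @param priming Apply the 100 Hz / 3 s priming burst.
#' @param hist_rate Postsynaptic rate of the assumed activity history (Hz).
#' @param distance,w_ampa,w_nmda Synapse parameters.
#' @param cable,soma,plast Model configuration.
#' @param seed Seed for the Poisson trains.
#' @return A `protocol_result`.
#' @export
run_rate_protocol <- function(post_rate, pre_rate = 10, duration = 30,
                              priming = FALSE, hist_rate = 10,
                              distance = 200, w_ampa = 200, w_nmda = 500,
                              cable = cable_config(), soma = soma_spec(),
                              plast = plasticity_config(), seed = 1) {
  ep0 <- measure_epsp(cable, soma, distance, w_ampa, w_nmda)
  a_bap <- event_voltage_integral(cable, soma, distance, w_ampa, w_nmda, "bap")
  a_epsp <- event_voltage_integral(cable, soma, distance, w_ampa, w_nmda, "epsp")
  u_bar0 <- cable$resting_potential +
    (hist_rate * a_bap + pre_rate * a_epsp) / 1000
  plast$u_bar0 <- u_bar0

  t0 <- if (priming) 3200 else 100
  pre <- t0 + poisson_train(pre_rate, duration, seed)
  post <- t0 + poisson_train(post_rate, duration, seed + 1L)
  m <- single_synapse_model(cable, soma, distance, w_ampa, w_nmda,
                            presyn_times = pre)
  if (priming) m <- schedule_ap(m, seq(100, 3090, by = 10))
  if (length(post) > 0) m <- elicit_postsynaptic_spike(m, post)
  dur <- t0 + duration * 1000 + 200
  r <- simulate_neuron(m, dur, plasticity = plast, record_dt = dur,
                       record_nodes = 0, syn_traces = FALSE, weight_dt = 1000)
  wf <- c(r$w_ampa_final[1], r$w_nmda_final[1])
  ep1 <- measure_epsp(cable, soma, distance, wf[1], wf[2])
  protocol_result("rate", list(pre_rate = pre_rate, post_rate = post_rate,
                               duration = duration, priming = priming),
                  ep0, ep1, c(w_ampa, w_nmda), wf, seed = seed,
                  extra = list(u_bar0 = u_bar0))
}

#' Voltage-clamp induction protocol
#'
#' The soma is clamped at a command voltage while a distal synapse (default
#' 700 um, NMDA only) is stimulated 100 times at 2 Hz. The clamp is ideal at
#' the soma; at the distal synapse its influence is weaker and local
#' synaptic currents still move the spine-head potential. With
#' `sigma_scaling`, the rule's noise amplitude sigma is scaled linearly with
#' the initial synaptic strength (`sigma^2` by `w_scale^2`), the
#' homosynaptic variant used to study depressed/potentiated synapses.
#'
#' @param command Clamp command voltage (mV).
#' @param n_stim Number of presynaptic stimuli.
#' @param stim_rate Stimulation rate (Hz).
#' @param distance,w_ampa,w_nmda Synapse parameters.
#' @param w_scale Multiplier on the initial weights (depressed < 1,
#'   potentiated > 1).
#' @param sigma_scaling Scale sigma with the initial strength.
#' @param cable,soma,plast Model configuration.
#' @return A `protocol_result`.
#' @export
run_voltage_clamp <- function(command, n_stim = 100, stim_rate = 2,
                              distance = 700, w_ampa = 0, w_nmda = 500,
                              w_scale = 1, sigma_scaling = FALSE,
                              cable = cable_config(), soma = soma_spec(),
                              plast = plasticity_config()) {
  wa <- w_ampa * w_scale
  wn <- w_nmda * w_scale
  ep0 <- measure_epsp(cable, soma, distance, wa, wn)
  pre <- 100 + (seq_len(n_stim) - 1) * 1000 / stim_rate
  m <- single_synapse_model(cable, soma, distance, wa, wn,
                            presyn_times = pre,
                            sigma2_scale = if (sigma_scaling) w_scale^2 else 1)
  m <- set_voltage_clamp(m, clamp_spec(command))
  dur <- max(pre) + 400
  r <- simulate_neuron(m, dur, plasticity = plast, record_dt = dur,
                       record_nodes = 0, syn_traces = FALSE, weight_dt = 1000)
  wf <- c(r$w_ampa_final[1], r$w_nmda_final[1])
  ep1 <- measure_epsp(cable, soma, distance, wf[1], wf[2])
  protocol_result("voltage_clamp",
                  list(command = command, n_stim = n_stim,
                       stim_rate = stim_rate, distance = distance,
                       w_scale = w_scale, sigma_scaling = sigma_scaling),
                  ep0, ep1, c(wa, wn), wf)
}

#' Weight calibration: conductance for a target somatic EPSP
#'
#' Bridges the strength unit of the population experiments (initial strength
#' stated as a somatic EPSP amplitude, mV) to the NMDA conductance of the
#' model: finds `w_nmda` such that a single test pulse from rest produces
#' the target EPSP peak at the soma. EPSP amplitude is nearly linear in the
#' weight at these amplitudes, so two fixed-point iterations suffice.
#'
#' @param target_mv Target EPSP peak (mV).
#' @param cable,soma Neuron configuration.
#' @param distance Synapse location (um).
#' @return Calibrated `w_nmda` (pS).
#' @export
calibrate_weight <- function(target_mv, cable = cable_config(),
                             soma = soma_spec(), distance = 200) {
  w <- 500
  for (i in 1:2) {
    ep <- measure_epsp(cable, soma, distance, 0, w)
    w <- w * target_mv / ep
  }
  w
}

#' Synapse-population growth protocol
#'
#' A population of synapses at a common dendritic distance receives
#' independent Poisson trains; the plasticity rule runs continuously, the
#' soma fires through its threshold mechanism, and the population weight
#' distribution is recorded at checkpoints. Strengths are reported as
#' somatic EPSP amplitudes (mV) via a probe-calibrated weight-to-EPSP curve;
#' synapses stronger than 10 mV are flagged for exclusion from skewness
#' statistics downstream.
#'
#' @param n_syn Number of synapses (>= 2).
#' @param distance Common location (um).
#' @param pre_rate Presynaptic rate per synapse (Hz).
#' @param w0 Initial strength of every synapse (mV, somatic EPSP).
#' @param duration Simulated time (s).
#' @param mode `"multiplicative"` or `"additive"` learning rule.
#' @param n_trials Independent repetitions (new spike trains per trial).
#' @param seed Master seed; per-trial and per-synapse seeds derive from it.
#' @param checkpoints Times (s) at which the population is recorded.
#' @param cable,soma,plast Model configuration.
#' @return Object of class `population_result`: per-trial matrices of
#'   weights (pS) and strengths (mV) at each checkpoint.
#' @export
run_population <- function(n_syn = 100, distance = 200, pre_rate = 3,
                           w0 = 0.16, duration = 300,
                           mode = c("multiplicative", "additive"),
                           n_trials = 1, seed = 1, checkpoints = NULL,
                           cable = cable_config(), soma = soma_spec(),
                           plast = plasticity_config()) {
  mode <- match.arg(mode)
  stopifnot(n_syn >= 2)
  plast$mode <- mode
  if (is.null(checkpoints)) {
    checkpoints <- unique(c(30, duration)[c(30, duration) <= duration])
  }
  w_init <- calibrate_weight(w0, cable, soma, distance)

  if (duration == 0) {
    # no stimulation: the population is still the initial delta peak
    trials <- replicate(n_trials, {
      w <- matrix(w_init, nrow = 1, ncol = n_syn,
                  dimnames = list("t0", NULL))
      s <- matrix(w0, nrow = 1, ncol = n_syn, dimnames = list("t0", NULL))
      list(weights = w, strengths = s, n_spikes = 0L)
    }, simplify = FALSE)
    return(structure(
      list(trials = trials, checkpoints = 0, n_syn = n_syn,
           distance = distance, pre_rate = pre_rate, w0 = w0,
           w_init = w_init, mode = mode, seed = seed),
      class = "population_result"
    ))
  }

  # weight -> somatic EPSP curve (monotone spline through probe points)
  make_strength_fun <- function(w_max) {
    grid <- unique(c(0, exp(seq(log(max(w_init / 4, 1)),
                                log(max(w_max * 1.1, w_init * 2)),
                                length.out = 14))))
    eps <- vapply(grid, function(w) {
      if (w == 0) 0 else measure_epsp(cable, soma, distance, 0, w)
    }, numeric(1))
    stats::splinefun(grid, eps, method = "hyman")
  }

  trials <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    trains <- lapply(seq_len(n_syn), function(s) {
      poisson_train(pre_rate, duration, seed + 7919L * (tr - 1L) + s)
    })
    m <- build_neuron(cable, soma)
    for (s in seq_len(n_syn)) {
      m <- attach_synapse(m, synapse(w_ampa = 0, w_nmda = w_init,
                                     distance = distance,
                                     presyn_times = trains[[s]]))
    }
    m$spiking <- TRUE
    r <- simulate_neuron(m, duration * 1000, plasticity = plast,
                         record_dt = duration * 1000, record_nodes = 0,
                         syn_traces = FALSE, weight_dt = 1000)
    idx <- vapply(checkpoints * 1000, function(tc) {
      which.min(abs(r$w_times - tc))
    }, integer(1))
    w_chk <- r$w_nmda[idx, , drop = FALSE]
    strength_of <- make_strength_fun(max(w_chk))
    s_chk <- matrix(strength_of(w_chk), nrow = length(idx))
    rownames(w_chk) <- rownames(s_chk) <- paste0("t", checkpoints)
    trials[[tr]] <- list(weights = w_chk, strengths = s_chk,
                         n_spikes = length(r$spikes))
  }
  structure(
    list(trials = trials, checkpoints = checkpoints, n_syn = n_syn,
         distance = distance, pre_rate = pre_rate, w0 = w0,
         w_init = w_init, mode = mode, seed = seed),
    class = "population_result"
  )
}

#' @export
print.population_result <- function(x, ...) {
  cat(sprintf(
    "<population_result> %d synapses x %d trial(s), %s rule, checkpoints at %s s\n",
    x$n_syn, length(x$trials), x$mode,
    paste(x$checkpoints, collapse = ", ")
  ))
  invisible(x)
}

#' Strengths of one checkpoint across trials
#'
#' @param pop A `population_result`.
#' @param checkpoint Checkpoint time (s).
#' @return List of strength vectors (mV), one per trial.
#' @export
population_strengths <- function(pop, checkpoint) {
  key <- paste0("t", checkpoint)
  lapply(pop$trials, function(tr) tr$strengths[key, ])
}
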