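#' Passive cable configuration
#'
#' Geometry and passive electrical constants of the reduced ball-and-stick
#' neuron: a lumped spherical soma plus a single unbranched apical cable.
#' Defaults are calibrated once so that the backpropagating action potential
#' attenuates and broadens with distance roughly as in a large pyramidal
#' cell (half-width about doubling between 200 and 600 um).
#'
#' @param n_compartments Number of dendritic compartments (>= 20).
#' @param total_length Cable length (um).
#' @param diam Cable diameter (um).
#' @param axial_resistivity Axial resistivity R_i (Ohm cm).
#' @param membrane_resistance Specific membrane resistance R_m (Ohm cm^2).
#' @param membrane_capacitance Specific membrane capacitance C_m (uF/cm^2).
#' @param resting_potential Resting potential (mV).
#' @param dt Integration step (ms), at most 0.1.
#' @param soma_diameter Diameter of the lumped spherical soma (um).
#' @return Object of class `cable_config`. The electrotonic length constant
#'   `lambda_um` is computed and stored.
#' @export
cable_config <- function(n_compartments = 60, total_length = 800, diam = 2,
                         axial_resistivity = 110, membrane_resistance = 30000,
                         membrane_capacitance = 1, resting_potential = -70,
                         dt = 0.1, soma_diameter = 20) {
  if (n_compartments < 20) stop("n_compartments must be >= 20", call. = FALSE)
  if (dt <= 0 || dt > 0.1) stop("dt must be in (0, 0.1] ms", call. = FALSE)
  if (any(c(total_length, diam, axial_resistivity, membrane_resistance,
            membrane_capacitance, soma_diameter) <= 0)) {
    stop("cable dimensions and constants must be positive", call. = FALSE)
  }
  lambda_um <- 100 * sqrt(membrane_resistance * diam / (4 * axial_resistivity))
  structure(
    list(n_compartments = as.integer(n_compartments),
         total_length = total_length, diam = diam,
         axial_resistivity = axial_resistivity,
         membrane_resistance = membrane_resistance,
         membrane_capacitance = membrane_capacitance,
         resting_potential = resting_potential, dt = dt,
         soma_diameter = soma_diameter, lambda_um = lambda_um),
    class = "cable_config"
  )
}

#' Somatic spike mechanism
#'
#' The somatic action potential is a stereotyped waveform (difference of two
#' exponentials, normalized to `amplitude` above rest) that is either
#' scheduled directly or triggered when the soma crosses `ap_threshold`.
#' The waveform is imposed through a strong conductance toward the command
#' voltage (dynamic-clamp style, peak `ap_gmax`, decaying as the squared
#' waveform shape): it dominates the membrane during the spike but hands
#' over smoothly to the passive dynamics in the tail, so depolarization can
#' accumulate between high-frequency spikes. The bAP propagates passively
#' into the dendrite, attenuating and broadening with distance.
#' Postsynaptic spikes are elicited by a somatic current pulse (default
#' 2 nA for 3 ms); the pulse is ineffective during the refractory period.
#' Threshold-triggered firing adapts: each spike raises the threshold by
#' `threshold_adapt_inc`, decaying with `threshold_adapt_tau`, which gives
#' the self-regulated moderate firing rates of a real soma without active
#' conductances.
#'
#' @param ap_threshold Spike threshold at rest (mV).
#' @param amplitude AP peak above rest (mV).
#' @param rise,decay AP waveform time constants (ms).
#' @param ap_gmax Peak conductance of the AP command drive (nS).
#' @param adp_amplitude Optional after-depolarizing somatic current per
#'   spike (pA), decaying with `adp_tau`; 0 by default.
#' @param adp_tau Decay time constant of the after-depolarization (ms).
#' @param threshold_adapt_inc Spike-triggered threshold increment (mV).
#' @param threshold_adapt_tau Decay time constant of threshold adaptation
#'   (ms).
#' @param injection_amplitude Eliciting current pulse (pA).
#' @param injection_duration Pulse duration (ms).
#' @param refractory Minimum interval between threshold-triggered spikes
#'   (ms); must outlast the suprathreshold part of the AP waveform.
#' @param window_factor The AP drive is evaluated for `window_factor *
#'   decay` ms after each spike.
#' @export
soma_spec <- function(ap_threshold = -60, amplitude = 85, rise = 0.3,
                      decay = 3.5, ap_gmax = 3000, adp_amplitude = 0,
                      adp_tau = 40, threshold_adapt_inc = 1,
                      threshold_adapt_tau = 300,
                      injection_amplitude = 2000,
                      injection_duration = 3, refractory = 18,
                      window_factor = 8) {
  if (rise >= decay) stop("rise must be shorter than decay", call. = FALSE)
  if (amplitude <= 0) stop("AP amplitude must be positive", call. = FALSE)
  structure(
    list(ap_threshold = ap_threshold, amplitude = amplitude,
         rise = rise, decay = decay, ap_gmax = ap_gmax,
         adp_amplitude = adp_amplitude, adp_tau = adp_tau,
         threshold_adapt_inc = threshold_adapt_inc,
         threshold_adapt_tau = threshold_adapt_tau,
         injection_amplitude = injection_amplitude,
         injection_duration = injection_duration, refractory = refractory,
         window = window_factor * decay),
    class = "soma_spec"
  )
}

#' Somatic voltage-clamp specification
#'
#' An ideal clamp: the soma is held exactly at `command_voltage` at every
#' step; distal compartments settle to the attenuated steady state, and
#' local synaptic currents still perturb the distal voltage.
#'
#' @param command_voltage Clamp command (mV).
#' @param node Clamped compartment (0 = soma; only the soma is supported).
#' @param active Logical.
#' @export
clamp_spec <- function(command_voltage, node = 0, active = TRUE) {
  if (node != 0) stop("only the somatic node can be clamped", call. = FALSE)
  structure(list(node = node, command_voltage = command_voltage,
                 active = active),
            class = "clamp_spec")
}

#' Build a reduced compartmental neuron
#'
#' Discretizes the cable and returns a model to which synapses, spike
#' schedules and a clamp can be attached before [simulate_neuron()].
#'
#' @param cable A [cable_config()].
#' @param soma A [soma_spec()].
#' @return Object of class `neuron_model`.
#' @export
build_neuron <- function(cable = cable_config(), soma = soma_spec()) {
  dx <- cable$total_length / cable$n_compartments
  structure(
    list(cable = cable, soma = soma,
         dx = dx,
         centers = (seq_len(cable$n_compartments) - 0.5) * dx,
         synapses = list(), clamp = NULL,
         injections = matrix(numeric(0), ncol = 3,
                             dimnames = list(NULL, c("t0", "dur", "amp"))),
         ap_times = numeric(), spiking = FALSE),
    class = "neuron_model"
  )
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf(
    "<neuron_model> soma + %d compartments over %g um (lambda = %.0f um), %d synapse(s)\n",
    x$cable$n_compartments, x$cable$total_length, x$cable$lambda_um,
    length(x$synapses)
  ))
  invisible(x)
}

#' Map a path distance to a compartment
#'
#' Deterministic mapping of a synapse location to the nearest compartment
#' center; errors beyond the cable length.
#'
#' @param model A `neuron_model`.
#' @param distance Path distance from the soma (um).
#' @return Compartment index (1-based along the dendrite).
#' @export
distance_to_compartment <- function(model, distance) {
  if (distance < 0 || distance > model$cable$total_length) {
    stop("synapse distance lies beyond the cable", call. = FALSE)
  }
  which.min(abs(model$centers - distance))
}

#' Attach a synapse to the neuron
#'
#' @param model A `neuron_model`.
#' @param syn A [synapse()]; its `distance` selects the compartment.
#' @return The updated model.
#' @export
attach_synapse <- function(model, syn) {
  stopifnot(inherits(model, "neuron_model"), inherits(syn, "synapse"))
  syn$node <- distance_to_compartment(model, syn$distance)
  model$synapses[[length(model$synapses) + 1]] <- syn
  model
}

#' Activate the somatic voltage clamp
#'
#' @param model A `neuron_model`.
#' @param clamp A [clamp_spec()].
#' @return The updated model.
#' @export
set_voltage_clamp <- function(model, clamp) {
  stopifnot(inherits(clamp, "clamp_spec"))
  model$clamp <- clamp
  model
}

#' Schedule an elicited postsynaptic spike
#'
#' Adds a somatic current pulse (amplitude and duration from the model's
#' [soma_spec()]) at time `t`; the pulse drives the soma over threshold and
#' triggers exactly one stereotyped action potential (the refractory period
#' covers the pulse). Overlapping injections merge additively.
#'
#' @param model A `neuron_model`.
#' @param t Pulse onset time(s) (ms); vectorized.
#' @return The updated model.
#' @export
elicit_postsynaptic_spike <- function(model, t) {
  add <- cbind(t0 = t, dur = model$soma$injection_duration,
               amp = model$soma$injection_amplitude)
  model$injections <- rbind(model$injections, add)
  model$spiking <- TRUE
  model
}

#' Schedule forced action-potential commands
#'
#' Bypasses the injection/threshold mechanism and stamps the stereotyped AP
#' waveform at the soma at the given times (used e.g. for high-frequency
#' priming bursts, where each pulse would fall in the previous AP's window).
#'
#' @param model A `neuron_model`.
#' @param t AP onset times (ms).
#' @return The updated model.
#' @export
schedule_ap <- function(model, t) {
  model$ap_times <- sort(c(model$ap_times, t))
  model
}

# internal: flatten model + plasticity into the engine's argument lists
engine_args <- function(model, plasticity) {
  cab <- model$cable
  som <- model$soma
  kin_vec <- function(k) c(k$tau_r, k$tau_d1, k$tau_d2, k$lam, k$norm, k$e_rev)
  syn_list <- lapply(model$synapses, function(s) {
    sp <- s$spine
    # neck axial resistance 4 R_i L / (pi d^2); R_i Ohm cm -> Ohm um via 1e4
    r_neck <- 4 * cab$axial_resistivity * 1e4 * sp$neck_length /
      (pi * sp$neck_diam^2)
    head_area <- pi * sp$head_diam * sp$head_length
    list(node = s$node,
         kin_ampa = kin_vec(s$kin_ampa), kin_nmda = kin_vec(s$kin_nmda),
         w_ampa = s$w_ampa, w_nmda = s$w_nmda,
         mg = c(s$mg$mg_out, s$mg$alpha, s$mg$beta),
         g_neck = 1e9 / r_neck,
         c_head = 0.01 * cab$membrane_capacitance * head_area,
         g_leak_head = 10 * head_area / cab$membrane_resistance,
         pre_times = as.numeric(s$presyn_times),
         sigma2_scale = s$sigma2_scale)
  })
  neuron <- list(
    n_comp = cab$n_compartments, total_length = cab$total_length,
    diam = cab$diam, ri = cab$axial_resistivity,
    rm = cab$membrane_resistance, cm = cab$membrane_capacitance,
    e_rest = cab$resting_potential, soma_diam = cab$soma_diameter,
    dt = cab$dt, spiking = isTRUE(model$spiking),
    v_th = som$ap_threshold, refractory = som$refractory,
    th_adapt_inc = som$threshold_adapt_inc,
    th_adapt_tau = som$threshold_adapt_tau,
    ap_amp = som$amplitude, ap_tau_r = som$rise, ap_tau_d = som$decay,
    ap_window = som$window, ap_gmax = som$ap_gmax,
    adp_amp = som$adp_amplitude, adp_tau = som$adp_tau
  )
  inj <- model$injections
  if (nrow(inj) > 1) inj <- inj[order(inj[, 1]), , drop = FALSE]
  events <- list(
    injections = inj, ap_times = model$ap_times,
    clamp_active = !is.null(model$clamp) && isTRUE(model$clamp$active),
    clamp_v = if (is.null(model$clamp)) 0 else model$clamp$command_voltage
  )
  list(neuron = neuron, synapses = syn_list,
       plasticity = plasticity_engine_list(plasticity, cab$resting_potential),
       events = events)
}

#' Simulate the neuron
#'
#' Integrates the passive cable with all attached synapses, scheduled
#' spikes/injections and clamp with the unconditionally stable implicit
#' (backward Euler) method, returning voltage traces, per-synapse spine-head
#' state (`u`, `u_dot`, `u_bar`) and weight trajectories.
#'
#' @param model A `neuron_model`.
#' @param duration Simulated time (ms).
#' @param plasticity A [plasticity_config()], or `NULL` for a passive run
#'   with plasticity frozen.
#' @param record_dt Trace sampling interval (ms); defaults to the
#'   integration step.
#' @param record_nodes Compartments to record (0 = soma), or `"all"`.
#' @param syn_traces Record spine-head traces per synapse.
#' @param weight_dt Weight-snapshot interval (ms).
#' @return Object of class `cable_sim`: a list with `times`, voltage matrix
#'   `v` (one column per recorded node), spine-head matrices, weight
#'   trajectories, final weights and triggered spike times.
#' @export
simulate_neuron <- function(model, duration, plasticity = NULL,
                            record_dt = NULL, record_nodes = 0,
                            syn_traces = TRUE, weight_dt = NULL) {
  stopifnot(inherits(model, "neuron_model"), duration > 0)
  dt <- model$cable$dt
  if (is.null(record_dt)) record_dt <- dt
  if (is.null(weight_dt)) weight_dt <- max(duration / 100, dt)
  if (identical(record_nodes, "all")) {
    record_nodes <- 0:model$cable$n_compartments
  }
  args <- engine_args(model, plasticity)
  res <- cpp_simulate(args$neuron, args$synapses, args$plasticity,
                      args$events, duration,
                      list(rec_dt = record_dt,
                           nodes = as.integer(record_nodes),
                           syn_traces = isTRUE(syn_traces),
                           weight_dt = weight_dt))
  res$record_nodes <- record_nodes
  res$dt <- dt
  class(res) <- "cable_sim"
  res
}

#' @export
print.cable_sim <- function(x, ...) {
  cat(sprintf(
    "<cable_sim> %.1f ms, %d recorded samples, %d synapse(s), %d triggered spike(s)\n",
    max(x$times), length(x$times), ncol(x$w_ampa), length(x$spikes)
  ))
  invisible(x)
}

#' Analytic steady-state profile of the finite cable
#'
#' Closed-form sealed-end solution used as an independent oracle for the
#' discretized cable: with the somatic end held at a steady offset `v0`
#' above rest, the offset at path distance `x` is
#' `v0 * cosh((L - x)/lambda) / cosh(L/lambda)`.
#'
#' @param cable A [cable_config()].
#' @param x Path distance(s) from the soma (um).
#' @param v0 Steady somatic offset from rest (mV).
#' @return Steady-state offset(s) from rest at `x` (mV).
#' @export
cable_steady_profile <- function(cable, x, v0 = 1) {
  L <- cable$total_length
  lam <- cable$lambda_um
  v0 * cosh((L - x) / lam) / cosh(L / lam)
}
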