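#' Receptor conductance kinetics
#'
#' Triple-exponential conductance time course of a glutamatergic receptor:
#' one rising exponential (`tau_r`) and two decaying exponentials
#' (`tau_d1`, `tau_d2`) mixed with fraction `lam`, scaled by `norm` so the
#' peak of the waveform is 1.
#'
#' @param tau_r Rise time constant (ms).
#' @param tau_d1,tau_d2 Fast and slow decay time constants (ms).
#' @param lam Fraction of the fast decay component, in `[0, 1]`.
#' @param norm Peak normalization factor.
#' @param e_rev Reversal potential (mV).
#' @return Object of class `receptor_kinetics`.
#' @export
receptor_kinetics <- function(tau_r, tau_d1, tau_d2, lam, norm, e_rev = 0) {
  if (!(tau_r < tau_d1 && tau_d1 <= tau_d2)) {
    stop("require tau_r < tau_d1 <= tau_d2", call. = FALSE)
  }
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]", call. = FALSE)
  if (norm <= 0) stop("norm must be positive", call. = FALSE)
  structure(
    list(tau_r = tau_r, tau_d1 = tau_d1, tau_d2 = tau_d2,
         lam = lam, norm = norm, e_rev = e_rev),
    class = "receptor_kinetics"
  )
}

#' @rdname receptor_kinetics
#' @details `ampa_kinetics()` and `nmda_kinetics()` return the default
#'   parameter sets (AMPA: 0.55/2.0/8.0 ms, lambda 0.8, N 2.00; NMDA:
#'   4.05/27.6/147.4 ms, lambda 0.5, N 1.36), both normalized to unit peak.
#' @export
ampa_kinetics <- function() {
  receptor_kinetics(tau_r = 0.55, tau_d1 = 2.0, tau_d2 = 8.0,
                    lam = 0.8, norm = 2.00, e_rev = 0)
}

#' @rdname receptor_kinetics
#' @export
nmda_kinetics <- function() {
  receptor_kinetics(tau_r = 4.05, tau_d1 = 27.6, tau_d2 = 147.4,
                    lam = 0.5, norm = 1.36, e_rev = 0)
}

#' Normalized conductance waveform
#'
#' `g(t) = N (lam exp(-t/tau_d1) + (1-lam) exp(-t/tau_d2) - exp(-t/tau_r))`,
#' zero at onset by construction and normalized to a unit maximum by `N`.
#' Superposition over multiple presynaptic spikes is additive.
#'
#' @param t_since_spike Time since the presynaptic spike (ms); vectorized.
#' @param kin A [receptor_kinetics()].
#' @return Dimensionless conductance value(s).
#' @export
conductance_waveform <- function(t_since_spike, kin) {
  if (any(t_since_spike < 0)) {
    stop("t_since_spike must be non-negative", call. = FALSE)
  }
  with(kin, norm * (lam * exp(-t_since_spike / tau_d1) +
                    (1 - lam) * exp(-t_since_spike / tau_d2) -
                    exp(-t_since_spike / tau_r)))
}

#' Magnesium-block parameters
#'
#' Voltage-dependent block of the NMDA receptor channel by extracellular
#' magnesium, parameterized as `(1 + [Mg]_o / beta * exp(-alpha u))^-1`
#' (Jahr-Stevens form). Defaults: `[Mg]_o` = 1 mM, `alpha` = 0.062 /mV,
#' `beta` = 3.57 mM.
#'
#' @param mg_out Extracellular magnesium concentration (mM).
#' @param alpha Voltage sensitivity (1/mV).
#' @param beta Half-block concentration scale (mM).
#' @export
mg_block_params <- function(mg_out = 1, alpha = 0.062, beta = 3.57) {
  if (any(c(mg_out, alpha, beta) <= 0)) {
    stop("all magnesium-block parameters must be positive", call. = FALSE)
  }
  structure(list(mg_out = mg_out, alpha = alpha, beta = beta),
            class = "mg_block_params")
}

#' NMDA unblock factor
#'
#' Fraction of NMDA conductance relieved from the magnesium block at
#' membrane potential `u`; strictly increasing in `u`, bounded in (0, 1).
#'
#' @param u Membrane potential (mV); vectorized.
#' @param mg A [mg_block_params()].
#' @export
mg_unblock <- function(u, mg = mg_block_params()) {
  1 / (1 + (mg$mg_out / mg$beta) * exp(-mg$alpha * u))
}

#' Spine geometry
#'
#' Dendritic spine dimensions; the neck couples the synapse to the dendritic
#' shaft through the axial resistance
#' `R_neck = 4 R_i L_neck / (pi d_neck^2)`. Defaults: neck 1 x 0.1 um,
#' head 0.6 x 0.3 um.
#'
#' @param neck_length,neck_diam Neck length and diameter (um).
#' @param head_length,head_diam Head length and diameter (um).
#' @export
spine_geometry <- function(neck_length = 1, neck_diam = 0.1,
                           head_length = 0.6, head_diam = 0.3) {
  dims <- c(neck_length, neck_diam, head_length, head_diam)
  if (any(dims <= 0)) stop("spine dimensions must be positive", call. = FALSE)
  structure(list(neck_length = neck_length, neck_diam = neck_diam,
                 head_length = head_length, head_diam = head_diam),
            class = "spine_geometry")
}

#' Synapse description
#'
#' Per-synapse state: receptor weights (pS), dendritic location, spine
#' geometry, kinetics and presynaptic spike times. Weights may optionally be
#' tracked as the product of a channel count and a single-channel
#' conductance (`w_R = N_R * g_R`), the decomposition used by the factor
#' dynamics in [step_factors()].
#'
#' @param w_ampa,w_nmda Receptor weights (pS). Default `w_nmda` 500 pS.
#' @param distance Path distance from the soma (um).
#' @param spine A [spine_geometry()].
#' @param kin_ampa,kin_nmda [receptor_kinetics()] for the two receptor types.
#' @param mg A [mg_block_params()].
#' @param presyn_times Presynaptic spike arrival times (ms), sorted.
#' @param n_channels,g_single Optional named lists (`ampa`, `nmda`) giving
#'   the factor decomposition; if supplied, `n * g` must match the weight.
#' @param sigma2_scale Per-synapse multiplier on the rule's noise intensity
#'   sigma^2 (used by the sigma-scaling homeostasis variant).
#' @return Object of class `synapse`.
#' @export
synapse <- function(w_ampa = 0, w_nmda = 500, distance = 200,
                    spine = spine_geometry(),
                    kin_ampa = ampa_kinetics(), kin_nmda = nmda_kinetics(),
                    mg = mg_block_params(), presyn_times = numeric(),
                    n_channels = NULL, g_single = NULL, sigma2_scale = 1) {
  if (w_ampa < 0 || w_nmda < 0) stop("weights must be >= 0", call. = FALSE)
  if (is.unsorted(presyn_times)) presyn_times <- sort(presyn_times)
  if (!is.null(n_channels)) {
    for (r in c("ampa", "nmda")) {
      w <- if (r == "ampa") w_ampa else w_nmda
      prod <- n_channels[[r]] * g_single[[r]]
      if (w > 0 && abs(prod - w) > 1e-9 * w) {
        stop("factor decomposition inconsistent: n * g != w for ", r,
             call. = FALSE)
      }
    }
  }
  structure(
    list(w_ampa = w_ampa, w_nmda = w_nmda, distance = distance,
         spine = spine, kin_ampa = kin_ampa, kin_nmda = kin_nmda,
         mg = mg, presyn_times = presyn_times,
         n_channels = n_channels, g_single = g_single,
         sigma2_scale = sigma2_scale),
    class = "synapse"
  )
}

#' @export
print.synapse <- function(x, ...) {
  cat(sprintf(
    "<synapse> %g um from soma, w_AMPA = %g pS, w_NMDA = %g pS, %d presyn spikes\n",
    x$distance, x$w_ampa, x$w_nmda, length(x$presyn_times)
  ))
  invisible(x)
}

#' Synaptic current components
#'
#' Current through each receptor type at time `t` for local membrane
#' potential `u`:
#' `I_R = w_R * g_R(t) * [unblock(u) for NMDA] * (E_R - u)`,
#' summed over all presynaptic spikes at or before `t`.
#' Units: weights in pS, voltages in mV, currents in pA
#' (1 nS x 1 mV = 1 pA).
#'
#' @param t Time (ms).
#' @param u Local membrane potential (mV).
#' @param syn A [synapse()].
#' @return List with `ampa`, `nmda` and `total` currents (pA).
#' @export
synaptic_current <- function(t, u, syn) {
  stopifnot(is.finite(u))
  past <- syn$presyn_times[syn$presyn_times <= t]
  g_of <- function(kin) {
    if (length(past) == 0) return(0)
    sum(conductance_waveform(t - past, kin))
  }
  # pS -> nS conversion so that conductance x driving force is in pA
  i_ampa <- syn$w_ampa * 1e-3 * g_of(syn$kin_ampa) * (syn$kin_ampa$e_rev - u)
  i_nmda <- syn$w_nmda * 1e-3 * g_of(syn$kin_nmda) * mg_unblock(u, syn$mg) *
    (syn$kin_nmda$e_rev - u)
  list(ampa = i_ampa, nmda = i_nmda, total = i_ampa + i_nmda)
}

#' Plasticity rule: weight derivative
#'
#' The differential-Hebbian learning rule: for receptor type R with total
#' synaptic current `I_R` through that type,
#' \deqn{\dot w_R = \eta\, \frac{I_R(t)}{C}\,
#'   \frac{\partial S^*_u}{\partial \dot u}}
#' with the regularized gradient from [plasticity_gradient()]. Exactly linear
#' in `I_R`; with the noise term removed it reduces to the differential-
#' Hebbian form `dw/dt ~ u_dot * I_R`.
#'
#' @param i_r Total current through the receptor type (pA).
#' @param state A [voltage_state()] at the synapse.
#' @param params A [gradient_params()] (eta in s, converted internally).
#' @param capacitance Effective local membrane capacitance (pF).
#' @return Weight derivative (pS/ms).
#' @export
weight_derivative <- function(i_r, state, params, capacitance) {
  if (capacitance <= 0) stop("capacitance must be positive", call. = FALSE)
  eta_ms <- params$eta * 1000
  eta_ms * (i_r / capacitance) * plasticity_gradient(state, params)
}

#' Coupled channel-number / conductance dynamics
#'
#' Integrates the factor system `dN/dt = eta_N g Omega`,
#' `dg/dt = eta_g N Omega` (classical RK4), the decomposition of the weight
#' change into receptor count and single-channel conductance. When the
#' factors are initialized with `g / N = sqrt(eta_g / eta_N)` the ratio is
#' conserved and the weight `w = N g` obeys the multiplicative rule
#' `dw/dt = 2 sqrt(eta_g eta_N) w Omega`. With `eta_g = 0` the weight change
#' becomes `dw/dt = eta_N g^2 Omega`, independent of `w` (additive limit).
#'
#' @param n0,g0 Initial channel count and single-channel conductance (pS).
#' @param omega Common gradient drive Omega, a constant or function of time.
#' @param dt Total integration time (ms).
#' @param eta_g,eta_n Factor learning rates.
#' @param n_steps RK4 steps.
#' @param ratio_tol Relative drift of `g/N` (when started at the conserved
#'   ratio) beyond which a consistency warning is raised.
#' @return List with final `n`, `g`, `w = n * g` and the ratio drift.
#' @export
step_factors <- function(n0, g0, omega, dt, eta_g, eta_n,
                         n_steps = 100, ratio_tol = 1e-6) {
  if (n0 <= 0 || g0 <= 0) stop("factors must start positive", call. = FALSE)
  om <- if (is.function(omega)) omega else function(t) omega
  h <- dt / n_steps
  y <- c(n = n0, g = g0)
  deriv <- function(t, y) c(eta_n * y[2] * om(t), eta_g * y[1] * om(t))
  t <- 0
  for (i in seq_len(n_steps)) {
    k1 <- deriv(t, y)
    k2 <- deriv(t + h / 2, y + h / 2 * k1)
    k3 <- deriv(t + h / 2, y + h / 2 * k2)
    k4 <- deriv(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  drift <- NA_real_
  if (eta_g > 0 && eta_n > 0) {
    target <- sqrt(eta_g / eta_n)
    if (abs(g0 / n0 - target) < 1e-12 * target) {
      drift <- abs(y[["g"]] / y[["n"]] - target) / target
      if (is.finite(drift) && drift > ratio_tol) {
        warning("factor ratio g/N drifted beyond tolerance: ",
                format(drift), call. = FALSE)
      }
    }
  }
  list(n = y[["n"]], g = y[["g"]], w = y[["n"]] * y[["g"]], ratio_drift = drift)
}
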