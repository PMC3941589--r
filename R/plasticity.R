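#' Plasticity configuration for simulations
#'
#' Couples the sparseness-gradient rule ([gradient_params()]) to the
#' compartmental simulation: each receptor-type weight follows
#' `dw_R/dt = eta (I_R / C_eff) dS*/du_dot` at its spine head, with the
#' running average `u_bar` advanced by the exact exponential filter.
#'
#' @param params A [gradient_params()] (noise sigma^2, regularization gamma,
#'   learning rate eta, measure).
#' @param tau_ubar Averaging time constant for `u_bar` (s). Default 30 s.
#' @param mode `"multiplicative"` (the current through the live weight drives
#'   the rule, so equal relative changes accrue at equal voltage histories)
#'   or `"additive"` (the drive current is evaluated with the weight frozen
#'   at its initial value, so increments are independent of the running
#'   weight).
#' @param c_eff Effective local membrane capacitance C of the rule (pF).
#'   This is the one calibrated constant of the reduced model: it sets the
#'   overall plasticity magnitude, chosen once so that a standard pairing
#'   protocol (7 pairings at 1 Hz) yields tens of percent change, and frozen.
#' @param enabled Logical; disabled for measurement probes.
#' @param u_bar0 Initial `u_bar` (mV); defaults to the resting potential,
#'   representing a quiet activity history. Protocols with a specified
#'   activity history (e.g. BCM conditioning) override it.
#' @export
plasticity_config <- function(params = gradient_params(), tau_ubar = 30,
                              mode = c("multiplicative", "additive"),
                              c_eff = 1.5, enabled = TRUE, u_bar0 = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "gradient_params"), tau_ubar > 0, c_eff > 0)
  structure(
    list(params = params, tau_ubar = tau_ubar, mode = mode, c_eff = c_eff,
         enabled = enabled, u_bar0 = u_bar0),
    class = "plasticity_config"
  )
}

# internal: engine representation; NULL means frozen probe
plasticity_engine_list <- function(pl, e_rest) {
  if (is.null(pl)) {
    return(list(enabled = FALSE, eta = 1.5, gamma = 10, sigma2 = 0.036,
                tau_ubar_ms = 30000, measure = 0L, mode = 0L, c_eff = 1,
                u_bar0 = e_rest))
  }
  stopifnot(inherits(pl, "plasticity_config"))
  list(enabled = isTRUE(pl$enabled),
       eta = pl$params$eta,
       gamma = pl$params$gamma,
       sigma2 = pl$params$sigma2,
       tau_ubar_ms = pl$tau_ubar * 1000,
       measure = if (pl$params$measure == "skewness") 0L else 1L,
       mode = if (pl$mode == "multiplicative") 0L else 1L,
       c_eff = pl$c_eff,
       u_bar0 = if (is.null(pl$u_bar0)) e_rest else pl$u_bar0)
}
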