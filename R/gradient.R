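#' Instantaneous membrane-voltage state
#'
#' Bundles the local membrane potential `u`, its slow running average `u_bar`
#' (the reference point for the sparseness measure) and its time derivative
#' `u_dot`. The mean-free potential `u_hat = u - u_bar` is derived, never
#' stored independently.
#'
#' @param u Membrane potential (mV).
#' @param u_bar Long-term mean potential (mV).
#' @param u_dot Time derivative of the membrane potential (mV/ms).
#' @return An object of class `voltage_state`.
#' @examples
#' st <- voltage_state(u = -65, u_bar = -70, u_dot = 0.5)
#' st$u_hat  # 5 mV
#' @export
voltage_state <- function(u, u_bar, u_dot) {
  vals <- c(u = u, u_bar = u_bar, u_dot = u_dot)
  if (!all(is.finite(vals))) {
    stop("all components of a voltage state must be finite", call. = FALSE)
  }
  structure(
    list(u = u, u_bar = u_bar, u_dot = u_dot, u_hat = u - u_bar),
    class = "voltage_state"
  )
}

#' @export
print.voltage_state <- function(x, ...) {
  cat(sprintf(
    "<voltage_state> u = %.3f mV, u_bar = %.3f mV, u_hat = %.3f mV, u_dot = %.3f mV/ms\n",
    x$u, x$u_bar, x$u_hat, x$u_dot
  ))
  invisible(x)
}

#' Parameters of the sparseness-gradient learning rule
#'
#' @param sigma2 Channel-noise intensity sigma^2 (mV^2/ms). Default 0.036.
#' @param gamma Regularization of the gradient denominator (mV). Must be
#'   positive; it stands in for the higher-order terms of the short-time
#'   expansion and keeps the gradient finite as `u_hat -> 0`. Default 10 mV.
#' @param delta Linearization window (ms) over which the voltage is treated as
#'   a drifting Wiener process. Used only by the moment and testing routines;
#'   the production rule absorbs the leading `delta^2` factor into `eta`.
#'   Default 0.1 ms.
#' @param eta Learning rate (s). Default 1.5 s.
#' @param measure Sparseness measure driving plasticity, `"skewness"` or
#'   `"kurtosis"`.
#' @return An object of class `gradient_params`.
#' @export
gradient_params <- function(sigma2 = 0.036, gamma = 10, delta = 0.1,
                            eta = 1.5, measure = c("skewness", "kurtosis")) {
  measure <- match.arg(measure)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (eta <= 0) stop("eta must be > 0", call. = FALSE)
  structure(
    list(sigma2 = sigma2, gamma = gamma, delta = delta, eta = eta,
         measure = measure),
    class = "gradient_params"
  )
}

#' Closed-form time-averaged Wiener moments
#'
#' Raw moments of the mean-free membrane potential, time-averaged over the
#' linearization window. Over a short window the voltage is approximated as
#' `u(t) = u_hat + u_dot * t + sigma * W(t)`, so at time `t` it is Gaussian
#' with mean `u_hat + u_dot * t` and variance `sigma^2 * t`; the returned
#' value is the average of the n-th Gaussian raw moment over `t` in
#' `[0, delta]`:
#' \deqn{\langle \hat u^2 \rangle_\delta = \hat u^2
#'   + \tfrac12(\sigma^2 + 2\hat u\dot u)\delta + \tfrac13\dot u^2\delta^2}
#' \deqn{\langle \hat u^3 \rangle_\delta = \hat u^3
#'   + \tfrac32 \hat u(\hat u\dot u + \sigma^2)\delta
#'   + (\hat u\dot u^2 + \dot u\sigma^2)\delta^2
#'   + \tfrac14\dot u^3\delta^3}
#'
#' @param n Moment order, 2 or 3.
#' @param state A [voltage_state()].
#' @param params A [gradient_params()]; `sigma2` and `delta` are used.
#' @return The time-averaged n-th raw moment (mV^n).
#' @seealso [monte_carlo_moments()] for a simulation-based check.
#' @export
wiener_moment <- function(n, state, params) {
  stopifnot(inherits(state, "voltage_state"), inherits(params, "gradient_params"))
  uh <- state$u_hat
  ud <- state$u_dot
  s2 <- params$sigma2
  d <- params$delta
  if (identical(as.integer(n), 2L)) {
    uh^2 + 0.5 * (s2 + 2 * uh * ud) * d + ud^2 * d^2 / 3
  } else if (identical(as.integer(n), 3L)) {
    uh^3 + 1.5 * uh * (uh * ud + s2) * d +
      (uh * ud^2 + ud * s2) * d^2 + 0.25 * ud^3 * d^3
  } else {
    stop("unsupported moment order: n must be 2 or 3", call. = FALSE)
  }
}

#' Instantaneous sample skewness of the membrane potential
#'
#' The stochastic "sample" of the skewness over the linearization window:
#' `<u_hat^3>_delta / <u_hat^2>_delta^(3/2)`, built from [wiener_moment()].
#'
#' @inheritParams wiener_moment
#' @return Dimensionless skewness sample.
#' @export
sample_skewness <- function(state, params) {
  m2 <- wiener_moment(2, state, params)
  if (m2 <= 0) {
    stop("sample skewness undefined: second moment is zero", call. = FALSE)
  }
  wiener_moment(3, state, params) / m2^1.5
}

#' Regularized skewness gradient
#'
#' Leading-order gradient of the sample skewness with respect to `u_dot`,
#' with the overall `delta^2` factor absorbed into the learning rate:
#' \deqn{\tfrac14(\dot u\hat u - 2\sigma^2)\,|\hat u|^3/(\hat u^6+\gamma^6).}
#' The terms of order `delta^0` do not depend on `u_dot` and the order-`delta`
#' terms cancel exactly; `gamma > 0` keeps the expression finite at
#' `u_hat = 0`. Setting `gamma = 0` in `params` is allowed here for testing
#' against the finite-difference oracle (then `u_hat` must be nonzero).
#'
#' @inheritParams wiener_moment
#' @return Gradient value (1/(mV ms)).
#' @export
skewness_gradient <- function(state, params) {
  uh <- state$u_hat
  num <- 0.25 * (state$u_dot * uh - 2 * params$sigma2) * abs(uh)^3
  den <- uh^6 + params$gamma^6
  if (den == 0) stop("u_hat and gamma both zero: gradient undefined", call. = FALSE)
  num / den
}

#' Regularized kurtosis gradient
#'
#' Analogue of [skewness_gradient()] for kurtosis as the sparseness measure:
#' \deqn{\tfrac23(\dot u\hat u - 1.5\sigma^2)\,\hat u^5/(\hat u^8+\gamma^8).}
#' Being built on an even moment, its depression branch does not flip sign
#' with the sign of `u_hat` the way the skewness rule does.
#'
#' @inheritParams wiener_moment
#' @return Gradient value (1/(mV ms)).
#' @export
kurtosis_gradient <- function(state, params) {
  uh <- state$u_hat
  num <- 2 / 3 * (state$u_dot * uh - 1.5 * params$sigma2) * uh^5
  den <- uh^8 + params$gamma^8
  if (den == 0) stop("u_hat and gamma both zero: gradient undefined", call. = FALSE)
  num / den
}

#' Gradient of the selected sparseness measure
#'
#' Dispatches to [skewness_gradient()] or [kurtosis_gradient()] according to
#' `params$measure`.
#'
#' @inheritParams wiener_moment
#' @export
plasticity_gradient <- function(state, params) {
  switch(params$measure,
    skewness = skewness_gradient(state, params),
    kurtosis = kurtosis_gradient(state, params)
  )
}

#' Advance the long-term mean potential
#'
#' One step of the exponentially weighted average
#' `d u_bar / dt = (u - u_bar) / tau_ubar`, advanced with the exact
#' exponential factor (not forward Euler), so the update is exact for
#' piecewise-constant `u`.
#'
#' @param u_bar Current mean potential (mV).
#' @param u Membrane potential held over the step (mV).
#' @param dt Step size (ms).
#' @param tau_ubar Averaging time constant (ms). Default 30 s.
#' @return Updated mean potential (mV).
#' @export
update_mean_potential <- function(u_bar, u, dt, tau_ubar = 30000) {
  if (dt <= 0 || tau_ubar <= 0) stop("dt and tau_ubar must be positive", call. = FALSE)
  u + (u_bar - u) * exp(-dt / tau_ubar)
}

#' Monte-Carlo moments of the drifting Wiener voltage process
#'
#' Simulation oracle for [wiener_moment()]: simulates `n_paths` trajectories
#' `u(t) = u_hat + u_dot t + sigma W(t)` on `[0, delta]` and returns the
#' time-averaged second and third raw moments with standard errors. Exact
#' Brownian increments are used; only the time average is discretized
#' (trapezoidal rule over `n_steps` sub-intervals).
#'
#' @inheritParams wiener_moment
#' @param n_paths Number of simulated paths (>= 1000).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param n_steps Quadrature sub-intervals per path.
#' @return List with `m2`, `m3` (estimates), `se2`, `se3` (standard errors),
#'   `n_paths`.
#' @export
monte_carlo_moments <- function(state, params, n_paths = 1e5, seed = 1,
                                n_steps = 200) {
  stopifnot(n_paths >= 1000)
  uh <- state$u_hat
  ud <- state$u_dot
  sig <- sqrt(params$sigma2)
  d <- params$delta
  h <- d / n_steps
  tgrid <- seq(0, d, length.out = n_steps + 1)
  drift <- uh + ud * tgrid
  # trapezoid weights for the time average (divided by delta)
  wts <- c(0.5, rep(1, n_steps - 1), 0.5) / n_steps

  chunk <- 5000L
  m2s <- numeric(n_paths)
  m3s <- numeric(n_paths)
  withr::with_seed(seed, {
    done <- 0L
    while (done < n_paths) {
      nb <- min(chunk, n_paths - done)
      dW <- matrix(stats::rnorm(nb * n_steps, sd = sig * sqrt(h)), nrow = nb)
      W <- cbind(0, t(apply(dW, 1L, cumsum)))
      U <- sweep(W, 2L, drift, "+")
      idx <- done + seq_len(nb)
      m2s[idx] <- as.vector((U^2) %*% wts)
      m3s[idx] <- as.vector((U^3) %*% wts)
      done <- done + nb
    }
  })
  list(
    m2 = mean(m2s), m3 = mean(m3s),
    se2 = stats::sd(m2s) / sqrt(n_paths),
    se3 = stats::sd(m3s) / sqrt(n_paths),
    n_paths = n_paths
  )
}
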