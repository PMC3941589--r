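#' Population skewness of synaptic strengths
#'
#' Third central moment over variance^(3/2) of the retained strengths,
#' using population moments (divide by n; a small-sample corrected variant
#' is available behind `sample_corrected`). Synapses stronger than the
#' exclusion threshold are removed first: strong synapses trigger
#' postsynaptic spikes during the measurement probe, which biases the
#' measured strength, so they are excluded from the statistics.
#'
#' @param weights Strengths (mV) or any positive weights.
#' @param exclusion_threshold Retain weights `<=` this value (default 10 mV);
#'   use `Inf` to retain everything.
#' @param sample_corrected Use the bias-corrected sample skewness estimator.
#' @return Sample skewness (dimensionless).
#' @export
population_skewness <- function(weights, exclusion_threshold = 10,
                                sample_corrected = FALSE) {
  w <- weights[weights <= exclusion_threshold]
  n <- length(w)
  if (n < 3) {
    stop("fewer than 3 weights retained: skewness undefined", call. = FALSE)
  }
  m <- mean(w)
  m2 <- mean((w - m)^2)
  m3 <- mean((w - m)^3)
  if (m2 == 0) return(0)   # point mass: symmetric by convention
  g1 <- m3 / m2^1.5
  if (sample_corrected) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Fit a distribution to the empirical CDF of synaptic strengths
#'
#' Least-squares fit of a lognormal or Gaussian cumulative distribution
#' function to the empirical CDF evaluated at the sorted strengths (step
#' convention k/n at the k-th sorted point); the CDF rather than the density
#' is used to avoid histogram binning choices. The fit quality is the root
#' mean square residual (RMSR) on the probability scale.
#'
#' @param weights Strengths (>= 10 points).
#' @param family `"lognormal"` or `"gaussian"`.
#' @return Object of class `fit_report` with `family`, `params` and `rmsr`.
#' @export
fit_cdf <- function(weights, family = c("lognormal", "gaussian")) {
  family <- match.arg(family)
  w <- weights
  if (family == "lognormal" && any(w <= 0)) {
    warning("non-positive weights excluded from lognormal fit",
            call. = FALSE)
    w <- w[w > 0]
  }
  if (length(w) < 10) stop("need at least 10 points", call. = FALSE)
  x <- sort(w)
  p_emp <- seq_along(x) / length(x)
  if (family == "lognormal") {
    start <- c(mean(log(x)), log(stats::sd(log(x)) + 1e-12))
    obj <- function(th) {
      sum((stats::plnorm(x, th[1], exp(th[2])) - p_emp)^2)
    }
  } else {
    start <- c(mean(x), log(stats::sd(x) + 1e-12))
    obj <- function(th) {
      sum((stats::pnorm(x, th[1], exp(th[2])) - p_emp)^2)
    }
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  params <- c(location = fit$par[1], scale = exp(fit$par[2]))
  structure(
    list(family = family, params = params,
         rmsr = sqrt(fit$value / length(x)), n = length(x)),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report:%s> location %.4g, scale %.4g, RMSR %.4g (n = %d)\n",
              x$family, x$params[1], x$params[2], x$rmsr, x$n))
  invisible(x)
}

#' EPSP peak amplitude from a somatic voltage trace
#'
#' `max(trace - baseline)` over the probe window. A trace crossing 0 mV
#' indicates a postsynaptic spike inside the probe window, which strongly
#' biases the measured strength; such probes raise an error.
#'
#' @param trace Somatic voltage samples (mV).
#' @param baseline Resting baseline (mV); the trace must start there.
#' @return Peak amplitude (mV).
#' @export
epsp_peak <- function(trace, baseline) {
  if (abs(trace[1] - baseline) > 1e-6) {
    stop("probe trace does not start at the baseline", call. = FALSE)
  }
  if (any(trace > 0)) {
    stop("measurement contaminated: postsynaptic spike in probe window",
         call. = FALSE)
  }
  max(trace - baseline)
}

#' Consistency of voltage and weight skewness
#'
#' Diagnostic (not an assertion) for the scaling relation between the
#' skewness of the membrane potential and the skewness of the synaptic
#' strengths: in the linear subthreshold regime, the voltage at any instant
#' is approximately a sum of `n` active synaptic strengths drawn iid from
#' the weight distribution, so standard cumulant scaling gives
#' `S_u ~ S_W / sqrt(n)`. With postsynaptic spiking the regime assumption
#' fails and the ratio is expected to drift.
#'
#' @param weights Synaptic strengths.
#' @param n_active Mean number of simultaneously active synapses.
#' @param s_u_measured Measured skewness of the (mean-free) voltage.
#' @return List with the weight skewness, predicted voltage skewness and
#'   measured/predicted ratio.
#' @export
su_sw_consistency <- function(weights, n_active, s_u_measured) {
  s_w <- population_skewness(weights, exclusion_threshold = Inf)
  predicted <- s_w / sqrt(n_active)
  list(s_w = s_w, n_active = n_active, s_u_predicted = predicted,
       s_u_measured = s_u_measured,
       ratio = s_u_measured / predicted)
}

#' Skewness of a population experiment across trials
#'
#' Applies [population_skewness()] with the exclusion rule to each trial of
#' a [run_population()] result at one checkpoint.
#'
#' @param pop A `population_result`.
#' @param checkpoint Checkpoint time (s).
#' @param exclusion_threshold Passed to [population_skewness()].
#' @return Numeric vector of per-trial skewness values.
#' @export
population_skewness_by_trial <- function(pop, checkpoint,
                                         exclusion_threshold = 10) {
  vapply(population_strengths(pop, checkpoint), population_skewness,
         numeric(1), exclusion_threshold = exclusion_threshold)
}

#' Plot the cumulative strength distribution with fitted CDFs
#'
#' @param x A `population_result`.
#' @param checkpoint Checkpoint time (s); defaults to the last.
#' @param trial Trial index.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.population_result <- function(x, checkpoint = NULL, trial = 1, ...) {
  if (is.null(checkpoint)) {
    checkpoint <- x$checkpoints[length(x$checkpoints)]
  }
  w <- population_strengths(x, checkpoint)[[trial]]
  w <- w[w > 0]
  xs <- sort(w)
  graphics::plot(xs, seq_along(xs) / length(xs), log = "x",
                 xlab = "synaptic strength (mV)", ylab = "cumulative density",
                 main = sprintf("%s rule, %g s", x$mode, checkpoint), ...)
  gr <- exp(seq(log(min(xs)), log(max(xs)), length.out = 200))
  ln <- fit_cdf(w, "lognormal")
  ga <- fit_cdf(w, "gaussian")
  graphics::lines(gr, stats::plnorm(gr, ln$params[1], ln$params[2]), lty = 1)
  graphics::lines(gr, stats::pnorm(gr, ga$params[1], ga$params[2]), lty = 3)
  graphics::legend("topleft", lty = c(1, 3), bty = "n",
                   legend = c(sprintf("lognormal (RMSR %.3g)", ln$rmsr),
                              sprintf("gaussian (RMSR %.3g)", ga$rmsr)))
  invisible(x)
}
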