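# brute-force population skewness: plain sums, no shared code with the
# package implementation
brute_skewness <- function(w) {
  n <- length(w)
  m <- sum(w) / n
  m2 <- sum((w - m)^2) / n
  m3 <- sum((w - m)^3) / n
  m3 / sqrt(m2)^3
}

# central finite difference of the sample skewness with respect to u_dot
fd_skew_gradient <- function(u_hat, u_dot, sigma2, delta, h = 1e-6) {
  pars <- gradient_params(sigma2 = sigma2, delta = delta)
  sp <- sample_skewness(voltage_state(u_hat, 0, u_dot + h), pars)
  sm <- sample_skewness(voltage_state(u_hat, 0, u_dot - h), pars)
  (sp - sm) / (2 * h)
}

# tiny neuron fixture for fast simulation tests
fast_cable <- function(...) cable_config(n_compartments = 30, dt = 0.1, ...)
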