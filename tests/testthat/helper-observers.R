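# Canonical parameter sets used across tests (plausible human values).

ci_ms_params <- function(...) {
  p <- c(beta_pre = -0.03, tau_a = 0.06, tau_v = 0.08, sigma_c1 = 0.05,
         sigma_c2 = 1, p_common = 0.7, criterion = 0.08, lambda = 0.02,
         alpha = 0.01)
  override(p, ...)
}

ci_mi_params <- function(...) {
  p <- c(beta_pre = -0.03, tau = 0.07, sigma_c1 = 0.05, sigma_c2 = 1,
         p_common = 0.7, criterion = 0.08, lambda = 0.02, alpha = 0.01)
  override(p, ...)
}

ac_ms_params <- function(...) {
  p <- c(beta_pre = -0.03, tau_a = 0.06, tau_v = 0.08, criterion = 0.08,
         lambda = 0.02, alpha = 0.3)
  override(p, ...)
}

corr_mi_params <- function(...) {
  p <- c(beta_pre = -0.03, tau = 0.07, criterion = 0.08, lambda = 0.02,
         alpha = 0.01)
  override(p, ...)
}

override <- function(p, ...) {
  ov <- c(...)
  p[names(ov)] <- ov
  p
}

# Quadrature of the measurement density split at the kink (each branch is a
# smooth exponential, which adaptive quadrature integrates accurately).
integrate_density <- function(model, s = 0, lower = -Inf, upper = Inf) {
  kink <- s + model$bias
  f <- function(m) measurement_density(model, m, s)
  stats::integrate(f, lower, kink, rel.tol = 1e-10)$value +
    stats::integrate(f, kink, upper, rel.tol = 1e-10)$value
}

# Tiny multinomial TOJ sampler used to build synthetic phase data in tests.
sample_phase_data <- function(probs, soas, n_rep, session = 1, phase = "pre",
                              adapter = 0, seed = 1) {
  set.seed(seed)
  resp <- unlist(lapply(seq_along(soas), function(i)
    sample(c("A", "S", "V"), n_rep, replace = TRUE, prob = probs[i, ])))
  data.frame(participant = "t", session = session, adapter_soa_s = adapter,
             phase = phase, trial = seq_len(n_rep * length(soas)),
             test_soa_s = rep(soas, each = n_rep), response = resp)
}
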