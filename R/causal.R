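#' Prior over audiovisual SOA under the two causal scenarios
#'
#' The causal-inference observer entertains two scenarios for each audiovisual
#' pair: a common cause (`C = 1`), under which the SOA prior is a zero-mean
#' Gaussian with small spread `sigma_c1`, and separate causes (`C = 2`), with
#' a much wider zero-mean Gaussian of spread `sigma_c2`.  `p_common` is the
#' prior probability of the common-cause scenario.  Both priors are centred on
#' zero (physically synchronous stimuli); no prior-mean parameter is exposed.
#'
#' @param sigma_c1 spread (s) of the common-cause SOA prior, > 0.
#' @param sigma_c2 spread (s) of the separate-causes SOA prior, > `sigma_c1`.
#' @param p_common prior probability of a common cause, in `[0, 1]`.
#' @return An object of class `"causal_prior"`.
#' @export
causal_prior <- function(sigma_c1, sigma_c2, p_common) {
  stopifnot(is.numeric(sigma_c1), length(sigma_c1) == 1L, is.finite(sigma_c1),
            is.numeric(sigma_c2), length(sigma_c2) == 1L, is.finite(sigma_c2),
            is.numeric(p_common), length(p_common) == 1L, is.finite(p_common))
  if (sigma_c1 <= 0 || sigma_c2 <= 0)
    stop("prior spreads must be strictly positive")
  if (sigma_c2 < sigma_c1)
    stop("'sigma_c2' (separate causes) must not be smaller than 'sigma_c1'")
  if (p_common < 0 || p_common > 1)
    stop("'p_common' must lie in [0, 1]")
  structure(list(sigma_c1 = sigma_c1, sigma_c2 = sigma_c2,
                 p_common = p_common),
            class = "causal_prior")
}

#' @export
print.causal_prior <- function(x, ...) {
  cat(sprintf(
    "Causal prior: sigma_C=1 = %.4g s, sigma_C=2 = %.4g s, p_common = %.3f\n",
    x$sigma_c1, x$sigma_c2, x$p_common))
  invisible(x)
}

#' Scenario-conditioned MAP estimate of the SOA
#'
#' Maximises the scenario-conditioned posterior `p(m | s) * N(s; 0, sigma^2)`
#' over the physical SOA `s`, where `p(m | s)` is the double-exponential
#' measurement density read as a likelihood in `s`.  The log-posterior is
#' piecewise linear-plus-quadratic with a kink at `s = m - bias`, so the
#' maximiser is one of three closed-form candidates: `-sigma^2/tau_v` (valid
#' when it lies at or above the kink), `sigma^2/tau_a` (valid below the kink),
#' or the kink itself.  Exactly one candidate is ever valid.
#'
#' @param model a [meas_model()] describing the observer's internal
#'   measurement distribution (its `bias` is the bias the observer attributes
#'   to its own measurements).
#' @param m measured SOA(s), seconds; vectorised.
#' @param sigma spread of the zero-mean Gaussian SOA prior, > 0.
#' @return MAP estimate(s) of the SOA in seconds.
#' @export
conditional_map_estimate <- function(model, m, sigma) {
  check_meas_model(model)
  stopifnot(length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) stop("'sigma' must be strictly positive")
  if (!all(is.finite(m))) stop("'m' must be finite")
  u <- m - model$bias
  lo <- -sigma^2 / model$tau_v  # stationary point on the upper branch (s >= u)
  hi <- sigma^2 / model$tau_a   # stationary point on the lower branch (s <  u)
  # exactly one of the three candidates applies; equivalent to clamping u
  pmin(pmax(u, lo), hi)
}

# log of the scenario likelihood P(m | C) = Int p(m|s) N(s; 0, sigma^2) ds.
# Exact: each branch integrates to an exponentially-modified-Gaussian term,
#   left  branch: exp(u/tau_v + sigma^2/(2 tau_v^2)) * Phi-bar((u + sigma^2/tau_v)/sigma)
#   right branch: exp(-u/tau_a + sigma^2/(2 tau_a^2)) * Phi((u - sigma^2/tau_a)/sigma)
# computed in log space for numerical stability. u = m - bias, vectorised.
log_scenario_lik <- function(u, tau_a, tau_v, sigma) {
  lt1 <- u / tau_v + sigma^2 / (2 * tau_v^2) +
    stats::pnorm((u + sigma^2 / tau_v) / sigma, lower.tail = FALSE,
                 log.p = TRUE)
  lt2 <- -u / tau_a + sigma^2 / (2 * tau_a^2) +
    stats::pnorm((u - sigma^2 / tau_a) / sigma, log.p = TRUE)
  mx <- pmax(lt1, lt2)
  mx + log(exp(lt1 - mx) + exp(lt2 - mx)) - log(tau_a + tau_v)
}

#' Posterior probability of a common cause
#'
#' Combines the scenario likelihoods `P(m | C)` — the measurement likelihood
#' integrated against the scenario's Gaussian SOA prior — with the prior
#' probability of a common cause via Bayes' rule.  The scenario likelihoods
#' are computed in closed form (exponentially-modified-Gaussian integrals,
#' evaluated in log space).
#'
#' @inheritParams conditional_map_estimate
#' @param prior a [causal_prior()].
#' @return Posterior probability (vectorised over `m`) in `[0, 1]`.
#' @export
posterior_common_cause <- function(model, m, prior) {
  check_meas_model(model)
  if (!inherits(prior, "causal_prior"))
    stop("'prior' must be a 'causal_prior' object")
  if (!all(is.finite(m))) stop("'m' must be finite")
  pc <- prior$p_common
  if (pc == 0) return(rep(0, length(m)))
  if (pc == 1) return(rep(1, length(m)))
  u <- m - model$bias
  l1 <- log_scenario_lik(u, model$tau_a, model$tau_v, prior$sigma_c1)
  l2 <- log_scenario_lik(u, model$tau_a, model$tau_v, prior$sigma_c2)
  if (any(!is.finite(l1) & !is.finite(l2)))
    stop("scenario likelihoods are numerically degenerate for these parameters")
  stats::plogis(log(pc) - log1p(-pc) + l1 - l2)
}

#' Causal-inference estimate of the SOA
#'
#' Runs the full causal-inference computation for measurement(s) `m`:
#' scenario-conditioned MAP estimates, posterior probability of a common
#' cause, and the model-averaged final estimate
#' `s_hat = s_hat_C1 * P(C=1|m) + s_hat_C2 * (1 - P(C=1|m))`.
#'
#' @inheritParams posterior_common_cause
#' @return A list of class `"causal_inference_result"` with numeric elements
#'   `map_c1`, `map_c2`, `posterior_c1` and `estimate`, each the length of
#'   `m`.  `estimate` always lies in the closed interval between `map_c1` and
#'   `map_c2`.
#' @export
infer_soa <- function(model, m, prior) {
  p1 <- posterior_common_cause(model, m, prior)
  m1 <- conditional_map_estimate(model, m, prior$sigma_c1)
  m2 <- conditional_map_estimate(model, m, prior$sigma_c2)
  structure(list(map_c1 = m1, map_c2 = m2, posterior_c1 = p1,
                 estimate = m1 * p1 + m2 * (1 - p1)),
            class = "causal_inference_result")
}

#' Causal-inference bias update
#'
#' After an exposure trial, the cumulative shift of the audiovisual bias is
#' moved by the learning rate times the discrepancy between the final SOA
#' estimate and the measurement: `delta + alpha * (estimate - m)`.
#'
#' @param delta cumulative bias shift before the trial (s).
#' @param m measured SOA on the trial (s).
#' @param estimate model-averaged SOA estimate for the trial (s).
#' @param alpha learning rate, >= 0.
#' @return Updated cumulative shift (s).
#' @export
ci_bias_update <- function(delta, m, estimate, alpha) {
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  delta + alpha * (estimate - m)
}

#' Posterior-weighted causal-inference bias update (model variant)
#'
#' Alternative update rule in which the shift is proportional to the posterior
#' probability of a common cause rather than to the estimate-measurement
#' discrepancy: `delta - alpha * posterior_c1 * m`.  Provided as an explicitly
#' flagged variant for recovery studies; it shares all other parameters with
#' the main causal-inference model.
#'
#' @inheritParams ci_bias_update
#' @param posterior_c1 posterior probability of a common cause on the trial.
#' @return Updated cumulative shift (s).
#' @export
ci_bias_update_posterior_variant <- function(delta, m, posterior_c1, alpha) {
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  delta - alpha * posterior_c1 * m
}
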