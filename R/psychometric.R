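#' Ternary TOJ response probabilities: measurement-readout observers
#'
#' For the asynchrony-contingent and asynchrony-correction observers the
#' estimate of the stimulus SOA equals the measured SOA, so the ternary
#' temporal-order-judgment probabilities have closed form in terms of the
#' measurement CDF `F` evaluated at the stimulus SOA `s`:
#' `Psi_V = lambda/3 + (1-lambda) * (1 - F(c))`,
#' `Psi_A = lambda/3 + (1-lambda) * F(-c)`, and
#' `Psi_S = 1 - Psi_V - Psi_A`.
#' Lapses are spread uniformly over the three responses.
#'
#' @param model a [meas_model()] with the observer's current bias.
#' @param s stimulus SOA(s) in seconds; vectorised.
#' @param criterion simultaneity criterion `c` (s), > 0; reports are
#'   "visual first" when the estimate exceeds `c`, "auditory first" below
#'   `-c`, "simultaneous" otherwise (ties at the criteria count as
#'   simultaneous).
#' @param lambda lapse rate in `[0, 1]`.
#' @return A matrix with one row per `s` and columns `p_auditory_first`,
#'   `p_simultaneous`, `p_visual_first`; rows sum to one.
#' @export
toj_probs_readout <- function(model, s, criterion, lambda) {
  check_decision(criterion, lambda)
  pv <- 1 - measurement_cdf(model, criterion, s)
  pa <- measurement_cdf(model, -criterion, s)
  lapse_mix(pa, 1 - pa - pv, pv, lambda)
}

check_decision <- function(criterion, lambda) {
  stopifnot(length(criterion) == 1L, is.finite(criterion),
            length(lambda) == 1L, is.finite(lambda))
  if (criterion <= 0) stop("'criterion' must be strictly positive")
  if (lambda < 0 || lambda > 1) stop("'lambda' must lie in [0, 1]")
}

lapse_mix <- function(pa, ps, pv, lambda) {
  out <- cbind(p_auditory_first = lambda / 3 + (1 - lambda) * pa,
               p_simultaneous   = lambda / 3 + (1 - lambda) * ps,
               p_visual_first   = lambda / 3 + (1 - lambda) * pv)
  out[, "p_simultaneous"] <-
    1 - out[, "p_auditory_first"] - out[, "p_visual_first"]
  out
}

# Causal-inference estimate as a function of the kink-relative measurement u,
# fully vectorised and exact; the workhorse behind infer_soa, the Monte-Carlo
# psychometric function, and the decision-region/lookup-table machinery.
ci_estimate_u <- function(u, tau_a, tau_v, prior) {
  m1 <- pmin(pmax(u, -prior$sigma_c1^2 / tau_v), prior$sigma_c1^2 / tau_a)
  m2 <- pmin(pmax(u, -prior$sigma_c2^2 / tau_v), prior$sigma_c2^2 / tau_a)
  pc <- prior$p_common
  if (pc == 0) return(m2)
  if (pc == 1) return(m1)
  l1 <- log_scenario_lik(u, tau_a, tau_v, prior$sigma_c1)
  l2 <- log_scenario_lik(u, tau_a, tau_v, prior$sigma_c2)
  w <- stats::plogis(log(pc) - log1p(-pc) + l1 - l2)
  m1 * w + m2 * (1 - w)
}

#' Ternary TOJ response probabilities: causal-inference observer (Monte Carlo)
#'
#' The distribution of causal-inference estimates has no closed form, so the
#' response probabilities are approximated by simulation: `n_samples`
#' measurements are drawn at stimulus SOA `s` (by inverse-CDF transform of
#' uniform deviates, so that a fixed seed yields an estimate that is smooth in
#' the parameters — common random numbers), each is mapped through the
#' causal-inference computation to an estimate, and the fractions of estimates
#' beyond the criteria give the pre-lapse probabilities.
#'
#' The measurements are generated under the model's current bias; the
#' observer's inference inverts the measurement distribution assuming the bias
#' `observer_bias` (default 0: the observer does not correct for its own
#' temporal bias, which is what lets recalibration shift the psychometric
#' functions).
#'
#' @inheritParams toj_probs_readout
#' @param prior a [causal_prior()].
#' @param n_samples number of Monte-Carlo measurements (default 10,000).
#' @param rng_seed optional seed for reproducible draws.
#' @param observer_bias bias the observer attributes to its measurements (s).
#' @param uniforms optional vector of uniform deviates in (0,1) to reuse
#'   across calls (overrides `n_samples` and `rng_seed`).
#' @return A one-row matrix with columns `p_auditory_first`,
#'   `p_simultaneous`, `p_visual_first` summing to one.
#' @seealso [toj_probs_ci_exact()] for the deterministic evaluation of the
#'   same probabilities.
#' @export
toj_probs_causal_inference <- function(model, s, criterion, lambda, prior,
                                       n_samples = 10000, rng_seed = NULL,
                                       observer_bias = 0, uniforms = NULL) {
  check_meas_model(model)
  check_decision(criterion, lambda)
  stopifnot(length(s) == 1L, is.finite(s))
  if (is.null(uniforms)) {
    stopifnot(n_samples >= 1)
    uniforms <- with_seed(rng_seed, stats::runif(n_samples))
  }
  m <- measurement_quantile(model, uniforms, s)
  est <- ci_estimate_u(m - observer_bias, model$tau_a, model$tau_v, prior)
  pv <- mean(est > criterion)
  pa <- mean(est < -criterion)
  lapse_mix(pa, 1 - pa - pv, pv, lambda)
}

# Decision regions of the causal-inference observer: the measurement-space
# sets {m : f(m) > c} and {m : f(m) < -c}, where f maps a measurement to the
# model-averaged estimate.  f is tabulated on a uniform grid, sign changes are
# bracketed and refined with uniroot on the exact f, and each region is
# returned as a 2-column matrix of interval endpoints (possibly +/-Inf).
# The estimate mapping saturates analytically outside [-lim, lim], so a wide
# fixed grid loses only measurement mass of order exp(-lim/tau).
ci_decision_regions <- function(tau_a, tau_v, prior, criterion,
                                observer_bias = 0, lim = 5, n_grid = 8001) {
  tab <- ci_estimate_table(tau_a, tau_v, prior, lim, n_grid)
  regions_from_table(tab, tau_a, tau_v, prior, criterion, observer_bias)
}

# Tabulated estimate mapping on a uniform grid (criterion-independent, so it
# can be cached across likelihood evaluations that only move the criterion).
ci_estimate_table <- function(tau_a, tau_v, prior, lim = 5, n_grid = 8001) {
  grid_u <- seq(-lim, lim, length.out = n_grid)
  list(grid = grid_u, values = ci_estimate_u(grid_u, tau_a, tau_v, prior))
}

regions_from_table <- function(tab, tau_a, tau_v, prior, criterion,
                               observer_bias = 0) {
  grid_u <- tab$grid
  f <- tab$values
  n_grid <- length(grid_u)
  cut_at <- function(thresh, above) {
    g <- if (above) f - thresh else thresh - f
    pos <- g > 0
    flips <- which(pos[-1] != pos[-n_grid])
    bounds <- vapply(flips, function(i) {
      stats::uniroot(function(u)
        if (above) ci_estimate_u(u, tau_a, tau_v, prior) - thresh
        else thresh - ci_estimate_u(u, tau_a, tau_v, prior),
        lower = grid_u[i], upper = grid_u[i + 1L],
        f.lower = g[i], f.upper = g[i + 1L], tol = 1e-11)$root
    }, numeric(1))
    edges <- c(if (pos[1]) -Inf, bounds, if (pos[n_grid]) Inf)
    if (length(edges) == 0)
      matrix(numeric(0), ncol = 2)
    else
      matrix(edges + observer_bias, ncol = 2, byrow = TRUE)
  }
  list(visual = cut_at(criterion, above = TRUE),
       auditory = cut_at(-criterion, above = FALSE),
       table = list(grid = grid_u + observer_bias, values = f))
}

# Total measurement mass of a union of disjoint intervals, for stimulus SOA
# centre(s); vectorised over centres (centre = s + current bias).
region_mass <- function(intervals, tau_a, tau_v, centres) {
  if (nrow(intervals) == 0) return(rep(0, length(centres)))
  mass <- rep(0, length(centres))
  for (r in seq_len(nrow(intervals))) {
    a <- intervals[r, 1]; b <- intervals[r, 2]
    fa <- if (is.finite(a)) fast_dexp_cdf(a - centres, tau_a, tau_v) else 0
    fb <- if (is.finite(b)) fast_dexp_cdf(b - centres, tau_a, tau_v) else 1
    mass <- mass + (fb - fa)
  }
  pmin(pmax(mass, 0), 1)
}

#' Ternary TOJ response probabilities: causal-inference observer (exact)
#'
#' Deterministic evaluation of the same probabilities that
#' [toj_probs_causal_inference()] approximates by simulation.  The estimate
#' mapping `s_hat = f(m)` is tabulated, the measurement-space regions where
#' `f(m) > c` and `f(m) < -c` are located by sign-change detection with root
#' refinement, and the response probabilities are the exact masses of those
#' regions under the closed-form measurement distribution.  This is the
#' infinite-sample limit of the Monte-Carlo procedure; it is smooth in the
#' parameters and is what the model likelihood uses.
#'
#' @inheritParams toj_probs_causal_inference
#' @param regions optional precomputed [ci_decision_regions()] result (reused
#'   across stimulus SOAs and bias values during fitting).
#' @return A matrix with one row per `s`, columns as in [toj_probs_readout()].
#' @export
toj_probs_ci_exact <- function(model, s, criterion, lambda, prior,
                               observer_bias = 0, regions = NULL) {
  check_meas_model(model)
  check_decision(criterion, lambda)
  if (is.null(regions))
    regions <- ci_decision_regions(model$tau_a, model$tau_v, prior, criterion,
                                   observer_bias)
  centres <- s + model$bias
  pv <- region_mass(regions$visual, model$tau_a, model$tau_v, centres)
  pa <- region_mass(regions$auditory, model$tau_a, model$tau_v, centres)
  lapse_mix(pa, 1 - pa - pv, pv, lambda)
}

#' Psychometric functions over a grid of test SOAs
#'
#' Evaluates the ternary response probabilities of any of the six observer
#' models over a grid of test SOAs, dispatching to the closed-form readout
#' computation or the causal-inference evaluation as appropriate.
#'
#' @param spec a [recal_model()] specification.
#' @param params named parameter vector for `spec` (see [model_parameters()]).
#' @param test_soas vector of stimulus SOAs (s); defaults to the 15-level
#'   design grid of [experiment_design()].
#' @param bias current audiovisual bias (s); defaults to `beta_pre`, i.e. the
#'   pre-test curve.  Pass `beta_pre + delta` for a recalibrated curve.
#' @param method for the causal-inference models, `"exact"` (decision-region
#'   evaluation, default) or `"mc"` (the 10,000-sample Monte-Carlo procedure).
#' @param n_samples,rng_seed Monte-Carlo settings when `method = "mc"`.
#' @return A data frame with columns `soa`, `p_auditory_first`,
#'   `p_simultaneous`, `p_visual_first`; one row per test SOA.
#' @export
psychometric_curve <- function(spec, params, test_soas = NULL, bias = NULL,
                               method = c("exact", "mc"), n_samples = 10000,
                               rng_seed = NULL) {
  check_spec(spec)
  method <- match.arg(method)
  params <- validate_params(spec, params)
  p <- expand_params(spec, params)
  if (is.null(test_soas)) test_soas <- experiment_design()$test_soas
  if (!length(test_soas)) stop("'test_soas' must be non-empty")
  if (is.null(bias)) bias <- p$beta_pre
  mm <- params_meas_model(p, bias)
  if (spec$update_rule != "causal_inference") {
    probs <- toj_probs_readout(mm, test_soas, p$criterion, p$lambda)
  } else if (method == "exact") {
    probs <- toj_probs_ci_exact(mm, test_soas, p$criterion, p$lambda,
                                params_prior(p))
  } else {
    probs <- do.call(rbind, lapply(seq_along(test_soas), function(i)
      toj_probs_causal_inference(mm, test_soas[i], p$criterion, p$lambda,
                                 params_prior(p), n_samples = n_samples,
                                 rng_seed = substream_seed(rng_seed, i))))
  }
  data.frame(soa = test_soas, probs)
}
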