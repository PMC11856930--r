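log_sum_exp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# Aggregate trial records into a (test SOA) x (response A/S/V) count matrix.
# The log-likelihood of a multinomial-response dataset is invariant to trial
# order, so all likelihood code works on these sufficient counts.
counts_by_soa <- function(data, soas = NULL) {
  if (!all(c("test_soa_s", "response") %in% names(data)))
    stop("trial records need 'test_soa_s' and 'response' columns")
  if (!all(data$response %in% c("A", "S", "V")))
    stop("responses must be 'A', 'S' or 'V'")
  if (is.null(soas)) soas <- sort(unique(data$test_soa_s))
  tab <- table(factor(data$test_soa_s, levels = soas),
               factor(data$response, levels = c("A", "S", "V")))
  matrix(as.numeric(tab), nrow = length(soas), ncol = 3,
         dimnames = list(NULL, c("A", "S", "V")))
}

# Branchless double-exponential CDF of the centred measurement noise,
# avoiding ifelse() in the likelihood hot path.
fast_dexp_cdf <- function(x, tau_a, tau_v) {
  neg <- x <= 0
  (tau_v * exp(pmin(x, 0) / tau_v) * neg +
     (tau_a + tau_v - tau_a * exp(-pmax(x, 0) / tau_a)) * !neg) /
    (tau_a + tau_v)
}

# Ternary probabilities for a vector of centres (centre = test SOA + current
# bias): the psychometric value depends on the stimulus and the bias only
# through their sum.  `regions` is required for the causal-inference rule.
probs_at_centres <- function(spec, p, centres, regions = NULL) {
  if (spec$update_rule == "causal_inference") {
    if (is.null(regions))
      regions <- ci_decision_regions(p$tau_a, p$tau_v, params_prior(p),
                                     p$criterion)
    pv <- region_mass(regions$visual, p$tau_a, p$tau_v, centres)
    pa <- region_mass(regions$auditory, p$tau_a, p$tau_v, centres)
  } else {
    pv <- 1 - fast_dexp_cdf(p$criterion - centres, p$tau_a, p$tau_v)
    pa <- fast_dexp_cdf(-p$criterion - centres, p$tau_a, p$tau_v)
  }
  lapse_mix(pa, 1 - pa - pv, pv, p$lambda)
}

# Sum of counts * log(prob); returns -Inf (never NaN) when a response with
# positive count has probability zero.
counts_loglik <- function(counts, probs) {
  lp <- log(probs)
  lp[counts == 0 & !is.finite(lp)] <- 0
  s <- sum(counts * lp)
  if (is.nan(s)) -Inf else s
}

#' Pre-test log-likelihood
#'
#' Log-likelihood of ternary TOJ responses under a single psychometric curve
#' evaluated at the model's default bias `beta_pre` — the pre-test curve,
#' shared across sessions because the bias resets to `beta_pre` before every
#' exposure phase.  Each trial contributes the log-probability of the response
#' given its test SOA.
#'
#' @param data trial records with at least `test_soa_s` and `response`
#'   columns (all rows are used; filter to the pre-test phase first when
#'   passing a full dataset).
#' @param spec a [recal_model()] specification.
#' @param params named parameter vector for `spec`.
#' @return The summed log-likelihood (may be `-Inf` when a realised response
#'   has probability zero, e.g. with `lambda = 0`).
#' @export
pretest_loglik <- function(data, spec, params) {
  check_spec(spec)
  params <- validate_params(spec, params)
  p <- expand_params(spec, params)
  soas <- sort(unique(data$test_soa_s))
  counts <- counts_by_soa(data, soas)
  counts_loglik(counts, probs_at_centres(spec, p, soas + p$beta_pre))
}

#' Post-test log-likelihood
#'
#' Log-likelihood of post-test responses, integrating over the unknown
#' cumulative bias shift realised in each session's exposure phase.  Per
#' session, the product of response probabilities over trials is evaluated at
#' `beta_post = beta_pre + shift` for each bin of the session's
#' [approximate_shift_distribution()], and the products are averaged against
#' the binned Gaussian weights as a Riemann sum (bin density times bin width),
#' in log space via a log-sum-exp over bins.
#'
#' @param data post-test trial records with `session`, `test_soa_s` and
#'   `response` columns.
#' @inheritParams pretest_loglik
#' @param shift_dists list of `"shift_distribution"` objects, one per session
#'   (in the order of `sort(unique(data$session))`).
#' @return The summed log-likelihood across sessions.
#' @export
posttest_loglik <- function(data, spec, params, shift_dists) {
  check_spec(spec)
  params <- validate_params(spec, params)
  p <- expand_params(spec, params)
  sessions <- sort(unique(data$session))
  if (length(shift_dists) != length(sessions))
    stop("need exactly one shift distribution per session")
  regions <- if (spec$update_rule == "causal_inference")
    ci_decision_regions(p$tau_a, p$tau_v, params_prior(p), p$criterion)
  total <- 0
  for (i in seq_along(sessions)) {
    rows <- data[data$session == sessions[i], , drop = FALSE]
    soas <- sort(unique(rows$test_soa_s))
    total <- total + session_post_loglik(spec, p, counts_by_soa(rows, soas),
                                         soas, shift_dists[[i]], regions)
  }
  total
}

session_post_loglik <- function(spec, p, counts, soas, sd_j, regions) {
  if (sd_j$point_mass) {
    pr <- probs_at_centres(spec, p, soas + p$beta_pre + sd_j$mean, regions)
    return(counts_loglik(counts, pr))
  }
  # bins with negligible Gaussian weight cannot affect the log-sum-exp
  keep <- sd_j$bin_weights > max(sd_j$bin_weights) * 1e-14
  if (!any(keep)) {   # all-underflow guard: collapse onto the Gaussian mean
    pr <- probs_at_centres(spec, p, soas + p$beta_pre + sd_j$mean, regions)
    return(counts_loglik(counts, pr))
  }
  sd_j$bin_centers <- sd_j$bin_centers[keep]
  sd_j$bin_weights <- sd_j$bin_weights[keep]
  n_bins <- length(sd_j$bin_centers)
  centres <- outer(soas, p$beta_pre + sd_j$bin_centers, "+")
  pr <- probs_at_centres(spec, p, as.numeric(centres), regions)
  ll_bins <- numeric(n_bins)
  for (r in 1:3) {
    lp <- log(pr[, r])
    lp[!is.finite(lp)] <- -745  # log of smallest double; avoids NaN in %*%
    ll_bins <- ll_bins + as.numeric(counts[, r] %*%
                                      matrix(lp, nrow = length(soas)))
  }
  out <- log_sum_exp(ll_bins + log(sd_j$bin_weights)) + log(sd_j$bin_width)
  if (is.nan(out)) -Inf else out
}

#' Joint pre/post log-likelihood of a recalibration dataset
#'
#' `log p(X | M, theta)` for a full dataset: the pre-test term plus the
#' post-test term, the latter integrating over per-session cumulative-shift
#' distributions regenerated by Monte-Carlo simulation of the exposure phase
#' (with common random numbers, so the result is deterministic given
#' `rng_seed` and varies smoothly with the parameters).
#'
#' @param data full trial table (columns `session`, `adapter_soa_s`, `phase`,
#'   `test_soa_s`, `response`).
#' @inheritParams pretest_loglik
#' @param rng_seed seed for the exposure-phase simulation noise.
#' @param n_reps exposure simulations per session (default 1000).
#' @param n_exposure exposure trials per simulation (default 250).
#' @param n_bins bins for the shift-distribution integral (default 100).
#' @return The joint log-likelihood, with attributes `pre` and `post`.
#' @export
joint_loglik <- function(data, spec, params, rng_seed = NULL, n_reps = 1000,
                         n_exposure = 250, n_bins = 100) {
  check_spec(spec)
  params <- validate_params(spec, params)
  p <- expand_params(spec, params)
  parts <- split_phases(data)
  noise <- with_seed(rng_seed, {
    n_tot <- length(parts$adapters) * n_reps * n_exposure
    list(ea = stats::rexp(n_tot), ev = stats::rexp(n_tot))
  })
  ll <- loglik_core(spec, p, parts, noise, n_reps, n_exposure, n_bins)
  structure(ll$total, pre = ll$pre, post = ll$post)
}

# Split a trial table into pre-test counts, per-session post-test counts and
# the per-session adapter SOAs; the shared sufficient statistics for fitting.
split_phases <- function(data) {
  need <- c("session", "adapter_soa_s", "phase", "test_soa_s", "response")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(data$phase %in% c("pre", "post")))
    stop("'phase' must be 'pre' or 'post'")
  sessions <- sort(unique(data$session))
  soas <- sort(unique(data$test_soa_s))
  pre <- data[data$phase == "pre", , drop = FALSE]
  post <- data[data$phase == "post", , drop = FALSE]
  adapters <- vapply(sessions, function(j) {
    a <- unique(data$adapter_soa_s[data$session == j])
    if (length(a) != 1) stop("session ", j, " has a non-constant adapter SOA")
    a
  }, numeric(1))
  list(soas = soas, sessions = sessions, adapters = adapters,
       pre_counts = counts_by_soa(pre, soas),
       post_counts = lapply(sessions, function(j)
         counts_by_soa(post[post$session == j, , drop = FALSE], soas)),
       n_trials = nrow(data))
}

# Shared likelihood core used by joint_loglik and the fitting objective.
# `cache` (an environment) memoizes the pieces that are invariant to a subset
# of the parameters, which saves most of the work in finite-difference
# gradient evaluations: the estimate table/regions depend only on the time
# constants, the causal prior and the criterion, and the exposure simulation
# does not depend on the decision parameters.
loglik_core <- function(spec, p, parts, noise, n_reps, n_exposure, n_bins,
                        cache = NULL) {
  regions <- NULL
  tab <- NULL
  ci <- spec$update_rule == "causal_inference"
  if (ci) {
    key_tab <- paste(p$tau_a, p$tau_v, p$sigma_c1, p$sigma_c2, p$p_common)
    if (!is.null(cache) && identical(cache$key_tab, key_tab)) {
      tab0 <- cache$tab
    } else {
      tab0 <- ci_estimate_table(p$tau_a, p$tau_v, params_prior(p),
                                n_grid = 4001)
      if (!is.null(cache)) {
        cache$key_tab <- key_tab
        cache$tab <- tab0
      }
    }
    key_reg <- paste(key_tab, p$criterion)
    if (!is.null(cache) && identical(cache$key_reg, key_reg)) {
      regions <- cache$regions
    } else {
      regions <- regions_from_table(tab0, p$tau_a, p$tau_v, params_prior(p),
                                    p$criterion)
      if (!is.null(cache)) {
        cache$key_reg <- key_reg
        cache$regions <- regions
      }
    }
    tab <- regions$table
  }
  key_exp <- paste(p$beta_pre, p$tau_a, p$tau_v, p$alpha,
                   if (ci) paste(p$sigma_c1, p$sigma_c2, p$p_common),
                   if (spec$update_rule == "asynchrony_correction")
                     p$criterion)
  if (!is.null(cache) && identical(cache$key_exp, key_exp)) {
    finals <- cache$finals
  } else {
    finals <- exposure_batch(spec, p, parts$adapters, n_reps, n_exposure,
                             noise = noise, tab = tab)
    if (!is.null(cache)) {
      cache$key_exp <- key_exp
      cache$finals <- finals
    }
  }
  # dynamically unstable learning rates (possible for the density-scaled
  # contingent rule) can blow up the simulated shifts; such parameters have
  # no support in the data
  if (!all(is.finite(finals)))
    return(list(total = -Inf, pre = -Inf, post = -Inf, shift_dists = NULL))
  shift_dists <- lapply(seq_along(parts$adapters), function(j)
    shift_distribution_from_sample(finals[, j], n_bins))
  pre <- counts_loglik(parts$pre_counts,
                       probs_at_centres(spec, p, parts$soas + p$beta_pre,
                                        regions))
  post <- 0
  for (i in seq_along(parts$sessions))
    post <- post + session_post_loglik(spec, p, parts$post_counts[[i]],
                                       parts$soas, shift_dists[[i]], regions)
  list(total = pre + post, pre = pre, post = post, shift_dists = shift_dists)
}
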