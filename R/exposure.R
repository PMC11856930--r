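#' Simulate one exposure-phase trajectory of the audiovisual bias
#'
#' Runs the trial-by-trial recalibration dynamics of an observer model through
#' one exposure phase: on each of `n_trials` trials a measurement of the
#' adapter SOA is drawn under the observer's *current* bias
#' `beta_i = beta_pre + delta_i`, the model's update rule is applied, and the
#' cumulative shift is recorded.
#'
#' @param spec a [recal_model()] specification.
#' @param params named parameter vector for `spec`.
#' @param adapter_soa the constant SOA presented during exposure (s).
#' @param n_trials number of exposure trials (default 250, the study design).
#' @param rng_seed optional seed.
#' @param variant `"main"` for the model's printed update rule, or
#'   `"posterior"` for the posterior-weighted causal-inference variant
#'   (causal-inference models only).
#' @return An object of class `"bias_trajectory"`: numeric vector of
#'   cumulative shifts of length `n_trials + 1` (first element 0), with
#'   attributes `adapter_soa` and `model`.
#' @export
simulate_exposure <- function(spec, params, adapter_soa, n_trials = 250,
                              rng_seed = NULL, variant = c("main", "posterior")) {
  check_spec(spec)
  variant <- match.arg(variant)
  params <- validate_params(spec, params)
  p <- expand_params(spec, params)
  stopifnot(length(adapter_soa) == 1L, is.finite(adapter_soa), n_trials >= 1)
  if (variant == "posterior" && spec$update_rule != "causal_inference")
    stop("the posterior-weighted variant applies to causal-inference models only")
  prior <- if (spec$update_rule == "causal_inference") params_prior(p)
  shifts <- numeric(n_trials + 1)
  with_seed(rng_seed, {
    ea <- stats::rexp(n_trials)
    ev <- stats::rexp(n_trials)
    delta <- 0
    for (i in seq_len(n_trials)) {
      bias_i <- p$beta_pre + delta
      m <- adapter_soa + bias_i + p$tau_a * ea[i] - p$tau_v * ev[i]
      delta <- switch(spec$update_rule,
        causal_inference = {
          if (variant == "main") {
            est <- ci_estimate_u(m, p$tau_a, p$tau_v, prior)
            ci_bias_update(delta, m, est, p$alpha)
          } else {
            obs <- meas_model(0, p$tau_a, p$tau_v)
            w <- posterior_common_cause(obs, m, prior)
            ci_bias_update_posterior_variant(delta, m, w, p$alpha)
          }
        },
        asynchrony_contingent =
          contingent_bias_update(params_meas_model(p, bias_i), delta, m,
                                 p$alpha),
        asynchrony_correction =
          correction_bias_update(delta, m, p$alpha, p$criterion),
        stop("unknown update rule: ", spec$update_rule))
      shifts[i + 1] <- delta
    }
  })
  structure(shifts, class = "bias_trajectory",
            adapter_soa = adapter_soa, model = spec$code)
}

#' @export
print.bias_trajectory <- function(x, ...) {
  cat(sprintf(
    "Exposure bias trajectory (model %s, adapter SOA %+.3f s, %d trials)\n",
    attr(x, "model"), attr(x, "adapter_soa"), length(x) - 1L))
  cat(sprintf("  final cumulative shift: %+.4f s\n", x[length(x)]))
  invisible(x)
}

# Lookup table of the causal-inference estimate mapping (or of the posterior
# probability of a common cause, for the variant rule) on a uniform grid.  The
# mapping saturates analytically beyond the grid, so the C++ kernel clamps.
ci_lookup_table <- function(p, variant = "main", lim = 5, n_grid = 8001) {
  grid <- seq(-lim, lim, length.out = n_grid)
  prior <- params_prior(p)
  vals <- if (variant == "main")
    ci_estimate_u(grid, p$tau_a, p$tau_v, prior)
  else {
    obs <- meas_model(0, p$tau_a, p$tau_v)
    posterior_common_cause(obs, grid, prior)
  }
  list(grid = grid, values = vals)
}

rule_code <- function(rule, variant = "main") {
  if (rule == "causal_inference" && variant == "posterior") return(4L)
  switch(rule, causal_inference = 1L, asynchrony_contingent = 2L,
         asynchrony_correction = 3L)
}

# Batch exposure simulation over sessions x repetitions (C++ kernel).
# `noise` may carry precomputed standard-exponential deviates (list with ea,
# ev of length >= n_sessions * n_reps * n_trials) for common-random-number
# reuse across likelihood evaluations; otherwise it is drawn from rng_seed.
# Returns an n_reps x n_sessions matrix of final cumulative shifts.
exposure_batch <- function(spec, p, adapter_soas, n_reps, n_trials,
                           rng_seed = NULL, noise = NULL, variant = "main",
                           tab = NULL) {
  n_tot <- length(adapter_soas) * n_reps * n_trials
  if (is.null(noise))
    noise <- with_seed(rng_seed,
                       list(ea = stats::rexp(n_tot), ev = stats::rexp(n_tot)))
  if (is.null(tab))
    tab <- if (spec$update_rule == "causal_inference")
      ci_lookup_table(p, variant)
    else list(grid = numeric(0), values = numeric(0))
  .exposure_batch_cpp(rule_code(spec$update_rule, variant),
                      as.numeric(adapter_soas),
                      p$beta_pre, p$tau_a, p$tau_v, p$alpha,
                      if (is.null(p$criterion)) 0 else p$criterion,
                      0, tab$grid, tab$values,
                      noise$ea, noise$ev, as.integer(n_reps),
                      as.integer(n_trials))
}

#' Gaussian-plus-bins approximation of the cumulative-shift distribution
#'
#' Simulates the exposure phase `n_reps` times, fits a Gaussian to the final
#' cumulative shifts by their empirical mean and standard deviation, and
#' discretises it into 100 equally spaced bins whose range is triple the range
#' of the Monte-Carlo sample (lower bound `min - (max - min)`, upper bound
#' `max + (max - min)`).  Bin weights are the Gaussian density at the bin
#' centres; the post-test likelihood integrates against them as a Riemann sum
#' (density times the uniform bin width).
#'
#' A degenerate sample with zero spread (e.g. learning rate 0) yields a
#' point-mass distribution with a single effective bin.
#'
#' @inheritParams simulate_exposure
#' @param n_reps number of independent exposure simulations (default 1000).
#' @param n_bins number of bins (default 100).
#' @return An object of class `"shift_distribution"`: list with elements
#'   `mean`, `sd`, `bin_centers`, `bin_weights` (Gaussian densities),
#'   `lower`, `upper`, `bin_width`, `sample_range`, `point_mass`, `n_reps`.
#' @export
approximate_shift_distribution <- function(spec, params, adapter_soa,
                                           n_reps = 1000, n_trials = 250,
                                           n_bins = 100, rng_seed = NULL) {
  check_spec(spec)
  params <- validate_params(spec, params)
  stopifnot(n_reps >= 2)
  p <- expand_params(spec, params)
  final <- exposure_batch(spec, p, adapter_soa, n_reps, n_trials,
                          rng_seed = rng_seed)[, 1]
  shift_distribution_from_sample(final, n_bins)
}

shift_distribution_from_sample <- function(final, n_bins = 100) {
  mn <- min(final); mx <- max(final)
  mu <- mean(final); sdev <- stats::sd(final)
  if (mx - mn <= 0 || sdev == 0) {
    return(structure(list(mean = mu, sd = 0, bin_centers = mu,
                          bin_weights = 1, lower = mu, upper = mu,
                          bin_width = 0, sample_range = c(mn, mx),
                          point_mass = TRUE, n_reps = length(final)),
                     class = "shift_distribution"))
  }
  lb <- mn - (mx - mn)
  ub <- mx + (mx - mn)
  width <- (ub - lb) / n_bins
  centers <- lb + width * (seq_len(n_bins) - 0.5)
  structure(list(mean = mu, sd = sdev, bin_centers = centers,
                 bin_weights = stats::dnorm(centers, mu, sdev),
                 lower = lb, upper = ub, bin_width = width,
                 sample_range = c(mn, mx), point_mass = FALSE,
                 n_reps = length(final)),
            class = "shift_distribution")
}

#' @export
print.shift_distribution <- function(x, ...) {
  if (x$point_mass)
    cat(sprintf("Cumulative-shift distribution: point mass at %+.4f s\n",
                x$mean))
  else
    cat(sprintf(
      "Cumulative-shift distribution: mean %+.4f s, sd %.4f s, %d bins on [%+.4f, %+.4f] s\n",
      x$mean, x$sd, length(x$bin_centers), x$lower, x$upper))
  invisible(x)
}
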