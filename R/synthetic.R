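#' Experiment design of a recalibration study
#'
#' Defaults reproduce the source study's design: nine sessions with adapter
#' SOAs 0, ±0.1, ±0.2, ±0.3 and ±0.7 s; fifteen test SOAs (±0.5 s and −0.3 to
#' 0.3 s in 0.05-s steps), each presented 20 times in the pre-test and 20
#' times in the post-test (300 temporal-order judgments per phase); and 250
#' exposure trials per session.  Negative SOAs denote auditory lead.
#'
#' @param adapter_soas adapter SOA per session (s).
#' @param test_soas test SOA grid (s).
#' @param n_rep_per_soa repetitions of each test SOA per phase.
#' @param n_exposure number of exposure trials.
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(adapter_soas = c(-0.7, -0.3, -0.2, -0.1, 0,
                                               0.1, 0.2, 0.3, 0.7),
                              test_soas = c(-0.5, seq(-0.3, 0.3, by = 0.05),
                                            0.5),
                              n_rep_per_soa = 20,
                              n_exposure = 250) {
  stopifnot(length(adapter_soas) >= 1, length(test_soas) >= 1,
            n_rep_per_soa >= 1, n_exposure >= 1)
  structure(list(adapter_soas = adapter_soas,
                 test_soas = sort(test_soas),
                 n_rep_per_soa = as.integer(n_rep_per_soa),
                 n_exposure = as.integer(n_exposure)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "Recalibration design: %d sessions, %d test SOAs x %d reps per phase, %d exposure trials\n",
    length(x$adapter_soas), length(x$test_soas), x$n_rep_per_soa,
    x$n_exposure))
  invisible(x)
}

# Plausible ground-truth ranges for synthetic observers; a subset of the
# fitting bounds, mirroring the between-participant spread typically reported
# for audiovisual ternary TOJ: biases within +/-120 ms, latency time constants
# 20-120 ms, simultaneity criteria from 40 to 300 ms, small lapse rates.  The
# asynchrony-contingent learning rate is larger because it multiplies a
# density (1/s).
default_truth_ranges <- function(spec) {
  lo <- c(beta_pre = -0.12, tau_a = 0.02, tau_v = 0.02, tau = 0.02,
          sigma_c1 = 0.02, sigma_c2 = 0.5, p_common = 0.3,
          criterion = 0.04, lambda = 0.005,
          alpha = if (spec$update_rule == "asynchrony_contingent") 0.05
                  else 0.003)
  hi <- c(beta_pre = 0.12, tau_a = 0.12, tau_v = 0.12, tau = 0.12,
          sigma_c1 = 0.15, sigma_c2 = 1.5, p_common = 0.9,
          criterion = 0.3, lambda = 0.06,
          alpha = if (spec$update_rule == "asynchrony_contingent") 0.6
                  else 0.02)
  rbind(lower = lo[spec$par_names], upper = hi[spec$par_names])
}

#' Draw a ground-truth observer for recovery studies
#'
#' Draws each free parameter of the model uniformly within plausible ranges
#' (by default a subset of the fitting bounds; see the package vignette).
#'
#' @param spec a [recal_model()] specification (or model code).
#' @param rng_seed optional seed.
#' @param ranges optional 2-row (`lower`, `upper`) matrix with one column per
#'   free parameter, overriding the defaults; must lie within the fitting
#'   bounds.
#' @return An object of class `"observer"`: list with elements `spec` and
#'   `params` (named vector), plus the seed used.
#' @export
generate_observer <- function(spec, rng_seed = NULL, ranges = NULL) {
  if (is.character(spec)) spec <- recal_model(spec)
  check_spec(spec)
  if (is.null(ranges)) ranges <- default_truth_ranges(spec)
  if (!all(spec$par_names %in% colnames(ranges)))
    stop("'ranges' must have one column per free parameter")
  ranges <- ranges[, spec$par_names, drop = FALSE]
  if (any(ranges["upper", ] < ranges["lower", ]))
    stop("empty range: upper bound below lower bound")
  if (any(ranges["lower", ] < spec$bounds["lower", ]) ||
      any(ranges["upper", ] > spec$bounds["upper", ]))
    stop("'ranges' must lie within the fitting bounds")
  params <- with_seed(rng_seed, {
    repeat {
      draw <- stats::runif(length(spec$par_names),
                           ranges["lower", ], ranges["upper", ])
      names(draw) <- spec$par_names
      if (spec$update_rule != "causal_inference" ||
          draw[["sigma_c1"]] < draw[["sigma_c2"]]) break
    }
    draw
  })
  structure(list(spec = spec, params = params, rng_seed = rng_seed),
            class = "observer")
}

#' @export
print.observer <- function(x, ...) {
  cat(sprintf("Synthetic observer (model %s)\n", x$spec$code))
  print(round(x$params, 4))
  invisible(x)
}

#' Simulate a complete recalibration experiment
#'
#' Generates trial-level ternary temporal-order judgments for every session of
#' the design.  Per session: pre-test responses are multinomial draws from the
#' observer's ternary response probabilities at the default bias `beta_pre`;
#' the exposure phase is then simulated once (a single realised trajectory,
#' as experienced by a real participant); and post-test responses are drawn at
#' `beta_post = beta_pre + delta_250`.  The bias resets to `beta_pre` at the
#' start of every session.
#'
#' @param observer an `"observer"` object from [generate_observer()], or a
#'   list with elements `spec` and `params`.
#' @param design an [experiment_design()].
#' @param rng_seed optional seed (sessions get independent substreams).
#' @param participant participant identifier stored in the trial table.
#' @return A data frame of trial records with columns `participant`,
#'   `session`, `adapter_soa_s`, `phase` (`"pre"`/`"post"`), `trial`,
#'   `test_soa_s`, `response` (`"A"`, `"S"`, `"V"`), carrying the realised
#'   per-session shifts as attribute `realized_shifts`.
#' @export
simulate_experiment <- function(observer, design = experiment_design(),
                                rng_seed = NULL,
                                participant = "synthetic-01") {
  spec <- check_spec(observer$spec)
  params <- validate_params(spec, observer$params)
  p <- expand_params(spec, params)
  stopifnot(inherits(design, "experiment_design"))
  sessions <- seq_along(design$adapter_soas)
  shifts <- numeric(length(sessions))
  recs <- vector("list", length(sessions))
  for (j in sessions) {
    traj <- simulate_exposure(spec, params, design$adapter_soas[j],
                              n_trials = design$n_exposure,
                              rng_seed = substream_seed(rng_seed, j, 1))
    shifts[j] <- traj[length(traj)]
    pre <- simulate_phase(spec, p, p$beta_pre, design,
                          substream_seed(rng_seed, j, 2))
    post <- simulate_phase(spec, p, p$beta_pre + shifts[j], design,
                           substream_seed(rng_seed, j, 3))
    recs[[j]] <- data.frame(
      participant = participant, session = j,
      adapter_soa_s = design$adapter_soas[j],
      phase = rep(c("pre", "post"), times = c(nrow(pre), nrow(post))),
      trial = c(seq_len(nrow(pre)), seq_len(nrow(post))),
      test_soa_s = c(pre$test_soa_s, post$test_soa_s),
      response = c(pre$response, post$response))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "realized_shifts") <- shifts
  out
}

# One TOJ phase: multinomial responses at each test SOA under a given bias.
simulate_phase <- function(spec, p, bias, design, seed) {
  mm <- params_meas_model(p, bias)
  probs <- if (spec$update_rule == "causal_inference")
    toj_probs_ci_exact(mm, design$test_soas, p$criterion, p$lambda,
                       params_prior(p))
  else
    toj_probs_readout(mm, design$test_soas, p$criterion, p$lambda)
  with_seed(seed, {
    soa <- rep(design$test_soas, each = design$n_rep_per_soa)
    resp <- unlist(lapply(seq_along(design$test_soas), function(i)
      sample(c("A", "S", "V"), design$n_rep_per_soa, replace = TRUE,
             prob = probs[i, ])))
    ord <- sample.int(length(soa))  # pseudo-randomised presentation order
    data.frame(test_soa_s = soa[ord], response = resp[ord])
  })
}
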