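#' Parameter-recovery study
#'
#' Draws synthetic observers from a model, simulates the full experiment for
#' each, refits the generating model, and correlates generating with recovered
#' parameter values.  The arrival-latency, bias and decision parameters
#' (`beta_pre`, time constants, `criterion`, `lambda`) are strongly
#' constrained by the 2 x 300 x 9 judgments and should recover with high
#' correlation; the causal-prior parameters and the learning rate are
#' reported but typically recover more weakly.
#'
#' @param n_observers number of synthetic observers (default 20).
#' @param model model code or [recal_model()] (default `"ci_ms"`).
#' @param design an [experiment_design()].
#' @param n_starts fit starts per observer (default 5).
#' @param rng_seed base seed; observers get independent substreams.
#' @param control fitting control list passed to [fit_recalibration()].
#' @param ranges optional truth ranges for [generate_observer()].
#' @return Object of class `"recovery_result"`: `draws` (long data frame of
#'   observer, parameter, truth, estimate), `correlations` (named vector),
#'   and the settings used.
#' @export
recover_parameters <- function(n_observers = 20, model = "ci_ms",
                               design = experiment_design(), n_starts = 5,
                               rng_seed = 1,
                               control = list(n_reps = 200, maxit = 60),
                               ranges = NULL) {
  spec <- if (is.character(model)) recal_model(model) else check_spec(model)
  rows <- vector("list", n_observers)
  for (i in seq_len(n_observers)) {
    obs <- generate_observer(spec, rng_seed = substream_seed(rng_seed, i, 11),
                             ranges = ranges)
    dat <- simulate_experiment(obs, design,
                               rng_seed = substream_seed(rng_seed, i, 13))
    fit <- fit_recalibration(dat, spec, n_starts = n_starts,
                             rng_seed = substream_seed(rng_seed, i, 17),
                             control = control)
    rows[[i]] <- data.frame(observer = i, parameter = spec$par_names,
                            truth = as.numeric(obs$params[spec$par_names]),
                            estimate = as.numeric(fit$par[spec$par_names]))
  }
  draws <- do.call(rbind, rows)
  cors <- vapply(spec$par_names, function(pn) {
    d <- draws[draws$parameter == pn, ]
    if (stats::sd(d$truth) == 0 || stats::sd(d$estimate) == 0) NA_real_
    else stats::cor(d$truth, d$estimate)
  }, numeric(1))
  structure(list(draws = draws, correlations = cors, model = spec$code,
                 n_observers = n_observers, n_starts = n_starts,
                 rng_seed = rng_seed),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Parameter recovery: model %s, %d observers, %d starts\n",
              x$model, x$n_observers, x$n_starts))
  cat("  truth-vs-estimate correlations:\n")
  print(round(x$correlations, 3))
  invisible(x)
}

#' @export
plot.recovery_result <- function(x, parameters = NULL, ...) {
  pars <- if (is.null(parameters)) unique(x$draws$parameter) else parameters
  n <- length(pars)
  old <- graphics::par(mfrow = c(ceiling(n / 3), min(n, 3)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (pn in pars) {
    d <- x$draws[x$draws$parameter == pn, ]
    graphics::plot(d$truth, d$estimate, pch = 16, xlab = "generating",
                   ylab = "recovered", main = pn)
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' Model-recovery study
#'
#' Simulates observers from each generating model, fits all candidate models
#' to every dataset, declares the winner by penalized likelihood (BIC), and
#' tabulates the confusion matrix — overall and collapsed over the precision
#' variants onto the three update-rule families.
#'
#' @param n_per_model synthetic observers per generating model (default 5).
#' @param models candidate (and generating) model codes.
#' @param design an [experiment_design()].
#' @param n_starts fit starts per model and dataset.
#' @param rng_seed base seed.
#' @param control fitting control list.
#' @return Object of class `"model_recovery_result"` with `confusion`
#'   (generating x winning counts), `family_confusion` (3 x 3), and `detail`.
#' @export
recover_models <- function(n_per_model = 5, models = MODEL_CODES,
                           design = experiment_design(), n_starts = 2,
                           rng_seed = 1,
                           control = list(n_reps = 100, maxit = 40)) {
  confusion <- matrix(0L, length(models), length(models),
                      dimnames = list(generating = models, winner = models))
  detail <- list()
  for (g in seq_along(models)) {
    gspec <- recal_model(models[g])
    for (i in seq_len(n_per_model)) {
      obs <- generate_observer(gspec,
                               rng_seed = substream_seed(rng_seed, g, i, 3))
      dat <- simulate_experiment(obs, design,
                                 rng_seed = substream_seed(rng_seed, g, i, 5))
      fits <- lapply(models, function(mc)
        fit_recalibration(dat, mc, n_starts = n_starts,
                          rng_seed = substream_seed(rng_seed, g, i, 7),
                          control = control))
      cmp <- compare_recal_fits(fits)
      winner <- cmp$model[1]
      confusion[models[g], winner] <- confusion[models[g], winner] + 1L
      detail[[length(detail) + 1]] <-
        data.frame(generating = models[g], observer = i, winner = winner,
                   best_bic = cmp$bic[1])
    }
  }
  fam <- function(code) sub("_m[si]$", "", code)
  fams <- unique(fam(models))
  family_confusion <- matrix(0L, length(fams), length(fams),
                             dimnames = list(generating = fams,
                                             winner = fams))
  for (g in models) for (w in models)
    family_confusion[fam(g), fam(w)] <-
      family_confusion[fam(g), fam(w)] + confusion[g, w]
  structure(list(confusion = confusion, family_confusion = family_confusion,
                 detail = do.call(rbind, detail), models = models,
                 n_per_model = n_per_model, rng_seed = rng_seed),
            class = "model_recovery_result")
}

#' @export
print.model_recovery_result <- function(x, ...) {
  cat(sprintf("Model recovery: %d observers per generating model\n",
              x$n_per_model))
  cat("confusion matrix (rows: generating, cols: winner):\n")
  print(x$confusion)
  cat("collapsed onto update-rule families:\n")
  print(x$family_confusion)
  invisible(x)
}
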