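#' Fit an observer model of temporal recalibration
#'
#' Maximum-likelihood fit of one of the six observer models to a full
#' recalibration dataset (pre- and post-test ternary TOJs of all sessions,
#' fitted jointly).  The joint log-likelihood is maximised by bound-constrained
#' quasi-Newton search (`optim` L-BFGS-B) from multiple starting points: one
#' data-driven start plus Latin-hypercube draws within the fitting bounds.
#' Exposure-phase simulation noise is drawn once per fit and reused across all
#' likelihood evaluations (common random numbers), so the objective is
#' deterministic and smooth and refitting with the same seed reproduces the
#' result exactly.
#'
#' For the causal-inference models the constraint `sigma_c1 < sigma_c2` is
#' enforced by optimising the spread gap `sigma_c2 - sigma_c1` instead of
#' `sigma_c2` itself.
#'
#' @param data trial table (see [read_trials()] or [simulate_experiment()]).
#' @param model model code (`"ci_ms"`, `"ci_mi"`, `"ac_ms"`, `"ac_mi"`,
#'   `"corr_ms"`, `"corr_mi"`) or a [recal_model()] object.
#' @param n_starts number of starting points (default 20).
#' @param rng_seed seed controlling starting points and simulation noise.
#' @param start optional named parameter vector (or list of vectors) used as
#'   additional starting point(s), e.g. a previous fit's estimates.
#' @param control list overriding fitting settings: `n_reps` (exposure
#'   simulations per session, default 1000), `n_exposure` (exposure trials,
#'   250), `n_bins` (shift-distribution bins, 100), `maxit` (joint-stage
#'   iteration cap, 200), `maxit_pre` (pre-test-stage cap, 40),
#'   `maxit_extra` (cap for the additional random starts; defaults to
#'   `maxit`), `staged` (run the cheap pre-test refinement first, default
#'   `TRUE`), `bracket` (add a second data-driven start on the other side of
#'   the criterion/prior ridge for causal-inference models, default `TRUE`)
#'   and `rel_tol` (optimizer relative tolerance, 1e-9).
#' @return An object of class `"recal_fit"` with components `par` (best
#'   estimates on the model's parameter space), `logLik`, `spec`, `starts`
#'   (per-start table), `control`, `rng_seed` and the dataset's sufficient
#'   statistics.  Methods: `print`, `summary`, `coef`, `logLik`, `predict`,
#'   `plot`, `simulate`.
#' @examples
#' \donttest{
#' obs <- generate_observer("corr_mi", rng_seed = 1)
#' dat <- simulate_experiment(obs, rng_seed = 1)
#' fit <- fit_recalibration(dat, "corr_mi", n_starts = 2, rng_seed = 1,
#'                          control = list(n_reps = 100, maxit = 60))
#' coef(fit)
#' }
#' @export
fit_recalibration <- function(data, model = "ci_ms", n_starts = 20,
                              rng_seed = 1, start = NULL, control = list()) {
  spec <- if (is.character(model)) recal_model(model) else check_spec(model)
  ctrl <- utils::modifyList(list(n_reps = 1000, n_exposure = 250,
                                 n_bins = 100, maxit = 200,
                                 staged = TRUE, maxit_pre = 40,
                                 maxit_extra = NULL, bracket = TRUE,
                                 rel_tol = 1e-9),
                            control)
  if (is.null(ctrl$maxit_extra)) ctrl$maxit_extra <- ctrl$maxit
  stopifnot(n_starts >= 1)
  parts <- split_phases(data)
  noise <- with_seed(substream_seed(rng_seed, 104729), {
    n_tot <- length(parts$adapters) * ctrl$n_reps * ctrl$n_exposure
    list(ea = stats::rexp(n_tot), ev = stats::rexp(n_tot))
  })

  tr <- internal_bounds(spec)
  cache <- new.env(parent = emptyenv())
  last <- list(theta = NULL, value = NULL)
  objective <- function(theta) {
    if (!is.null(last$theta) && identical(theta, last$theta))
      return(last$value)
    p <- expand_params(spec, from_internal(spec, theta))
    ll <- loglik_core(spec, p, parts, noise, ctrl$n_reps, ctrl$n_exposure,
                      ctrl$n_bins, cache = cache)$total
    if (!is.finite(ll)) ll <- -1e10
    last <<- list(theta = theta, value = ll)
    ll
  }
  # forward-difference gradient (the objective is deterministic and smooth
  # thanks to common random numbers, and the memoized pieces make the
  # one-sided scheme cheap)
  h <- pmax((tr["upper", ] - tr["lower", ]) * 1e-4, 1e-6)
  gradient <- function(theta) {
    f0 <- objective(theta)
    vapply(seq_along(theta), function(i) {
      ti <- theta
      if (ti[i] + h[i] <= tr["upper", i]) {
        ti[i] <- ti[i] + h[i]
        (objective(ti) - f0) / h[i]
      } else {
        ti[i] <- ti[i] - h[i]
        (f0 - objective(ti)) / h[i]
      }
    }, numeric(1))
  }

  # Cheap pre-test-only objective used by the staged search: every parameter
  # except the learning rate enters the pre-test curve, and evaluating it
  # needs no exposure simulation.
  i_alpha <- which(colnames(tr) == "alpha")
  pre_objective <- function(theta_pre, alpha) {
    theta <- c(theta_pre, alpha)
    names(theta) <- colnames(tr)
    p <- expand_params(spec, from_internal(spec, theta))
    regions <- NULL
    if (spec$update_rule == "causal_inference") {
      key_tab <- paste(p$tau_a, p$tau_v, p$sigma_c1, p$sigma_c2, p$p_common)
      if (!identical(cache$key_tab, key_tab)) {
        cache$key_tab <- key_tab
        cache$tab <- ci_estimate_table(p$tau_a, p$tau_v, params_prior(p),
                                       n_grid = 4001)
      }
      key_reg <- paste(key_tab, p$criterion)
      if (identical(cache$key_reg, key_reg)) regions <- cache$regions
      else {
        regions <- regions_from_table(cache$tab, p$tau_a, p$tau_v,
                                      params_prior(p), p$criterion)
        cache$key_reg <- key_reg
        cache$regions <- regions
      }
    }
    ll <- counts_loglik(parts$pre_counts,
                        probs_at_centres(spec, p, parts$soas + p$beta_pre,
                                         regions))
    if (!is.finite(ll)) -1e10 else ll
  }

  # Bound-constrained quasi-Newton searches via the PORT routines (nlminb),
  # which evaluate the (finite-difference) gradient once per iteration rather
  # than at every line-search point.
  optimize_start <- function(theta0, maxit = ctrl$maxit) {
    scale_of <- function(idx) 5 / (tr["upper", idx] - tr["lower", idx])
    if (ctrl$staged) {
      h_pre <- h[-i_alpha]
      pre_gradient <- function(theta_pre, alpha) {
        f0 <- pre_objective(theta_pre, alpha)
        vapply(seq_along(theta_pre), function(i) {
          ti <- theta_pre
          if (ti[i] + h_pre[i] <= tr["upper", -i_alpha][i]) {
            ti[i] <- ti[i] + h_pre[i]
            (pre_objective(ti, alpha) - f0) / h_pre[i]
          } else {
            ti[i] <- ti[i] - h_pre[i]
            (f0 - pre_objective(ti, alpha)) / h_pre[i]
          }
        }, numeric(1))
      }
      pre_opt <- tryCatch(
        stats::nlminb(theta0[-i_alpha],
                      function(th, alpha) -pre_objective(th, alpha),
                      gradient = function(th, alpha)
                        -pre_gradient(th, alpha),
                      alpha = theta0[[i_alpha]],
                      lower = tr["lower", -i_alpha],
                      upper = tr["upper", -i_alpha],
                      scale = scale_of(-i_alpha),
                      control = list(iter.max = ctrl$maxit_pre,
                                     eval.max = 3 * ctrl$maxit_pre,
                                     rel.tol = 1e-9)),
        error = function(e) NULL)
      if (!is.null(pre_opt)) theta0[-i_alpha] <- pre_opt$par
      # coarse learning-rate initialisation along the alpha axis
      a_grid <- unique(c(theta0[[i_alpha]],
                         tr["lower", i_alpha] +
                           (tr["upper", i_alpha] - tr["lower", i_alpha]) *
                           c(0.01, 0.03, 0.08, 0.2, 0.5)))
      a_ll <- vapply(a_grid, function(a) {
        th <- theta0; th[i_alpha] <- a; objective(th)
      }, numeric(1))
      theta0[i_alpha] <- a_grid[which.max(a_ll)]
    }
    opt <- stats::nlminb(theta0, function(th) -objective(th),
                         gradient = function(th) -gradient(th),
                         lower = tr["lower", ], upper = tr["upper", ],
                         scale = scale_of(seq_len(ncol(tr))),
                         control = list(iter.max = maxit,
                                        eval.max = 3 * maxit,
                                        rel.tol = ctrl$rel_tol))
    list(par = opt$par, value = -opt$objective,
         convergence = opt$convergence)
  }

  starts <- make_starts(spec, parts, n_starts, rng_seed, start,
                        bracket = ctrl$bracket)
  n_primary <- attr(starts, "n_primary")
  runs <- lapply(seq_along(starts), function(i) {
    theta0 <- to_internal(spec, starts[[i]])
    f0 <- objective(theta0)
    opt <- tryCatch(
      optimize_start(theta0, maxit = if (i <= n_primary) ctrl$maxit
                                     else ctrl$maxit_extra),
      error = function(e) NULL)
    if (is.null(opt) || opt$value < f0)
      # keep the starting point when the staged schedule ends below it
      list(par = starts[[i]], value = f0,
           convergence = if (is.null(opt)) 99L else 98L)
    else
      list(par = from_internal(spec, opt$par), value = opt$value,
           convergence = opt$convergence)
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  if (all(vals <= -1e10))
    stop("no starting point produced a finite joint log-likelihood; ",
         "check the data and model specification")
  best <- which.max(vals)
  if (best != 1 && ctrl$maxit_extra < ctrl$maxit) {
    # a shortened search won; polish it with the full iteration budget
    opt <- tryCatch(optimize_start(to_internal(spec, runs[[best]]$par)),
                    error = function(e) NULL)
    if (!is.null(opt) && opt$value > vals[best]) {
      runs[[best]] <- list(par = from_internal(spec, opt$par),
                           value = opt$value, convergence = opt$convergence)
      vals[best] <- opt$value
    }
  }
  starts_tab <- data.frame(start = seq_along(runs), loglik = vals,
                           convergence = vapply(runs, `[[`, integer(1),
                                                "convergence"))
  structure(list(par = runs[[best]]$par, logLik = vals[best], spec = spec,
                 starts = starts_tab, best_start = best, control = ctrl,
                 rng_seed = rng_seed, parts = parts,
                 n_obs = parts$n_trials,
                 data_fingerprint = data_fingerprint(parts)),
            class = "recal_fit")
}

data_fingerprint <- function(parts) {
  c(n = parts$n_trials, sessions = length(parts$sessions),
    checksum = sum(parts$pre_counts * seq_along(parts$pre_counts)) +
      sum(vapply(parts$post_counts, function(m)
        sum(m * seq_along(m)), numeric(1))))
}

# Internal optimisation space: identical to the model's parameter space except
# that sigma_c2 is replaced by the gap sigma_c2 - sigma_c1 (kept positive by
# its bounds), which makes the ordering constraint a box constraint.
internal_bounds <- function(spec) {
  b <- spec$bounds
  if (spec$update_rule == "causal_inference") {
    colnames(b)[colnames(b) == "sigma_c2"] <- "sigma_gap"
    b["lower", "sigma_gap"] <- 0.045
    b["upper", "sigma_gap"] <- 2.7
  }
  b
}

to_internal <- function(spec, params) {
  th <- params[spec$par_names]
  if (spec$update_rule == "causal_inference") {
    gap <- min(max(th[["sigma_c2"]] - th[["sigma_c1"]], 0.045), 2.7)
    th[["sigma_c2"]] <- gap
    names(th)[names(th) == "sigma_c2"] <- "sigma_gap"
  }
  th
}

from_internal <- function(spec, theta) {
  if (spec$update_rule == "causal_inference") {
    theta[["sigma_gap"]] <- theta[["sigma_gap"]] + theta[["sigma_c1"]]
    names(theta)[names(theta) == "sigma_gap"] <- "sigma_c2"
  }
  theta[spec$par_names]
}

# Data-driven starts (moments of the pre-test counts) plus Latin-hypercube
# draws within the bounds.  User-supplied starts are prepended.  For the
# causal-inference rule two moment starts bracket the criterion/prior ridge
# (a wide criterion with a weak common-cause prior is nearly exchangeable
# with a narrow criterion and a strong prior), so the likelihood — not the
# initialisation — picks the side.
make_starts <- function(spec, parts, n_starts, rng_seed, start = NULL,
                        bracket = TRUE) {
  user <- if (is.null(start)) list()
  else if (is.list(start) && !is.numeric(start)) start
  else list(start)
  user <- lapply(user, function(s) validate_params(spec, s))
  out <- c(user, list(moment_start(spec, parts)))
  if (bracket && spec$update_rule == "causal_inference" &&
      n_starts > length(out)) {
    alt <- out[[length(out)]]
    alt[["criterion"]] <- max(alt[["criterion"]] * 0.5,
                              spec$bounds["lower", "criterion"] + 1e-6)
    alt[["p_common"]] <- 0.85
    out <- c(out, list(alt))
  }
  n_primary <- length(out)
  k <- n_starts - length(out)
  if (k > 0) {
    b <- spec$bounds
    lh <- with_seed(substream_seed(rng_seed, 7919),
                    lhs::randomLHS(k, length(spec$par_names)))
    for (i in seq_len(k)) {
      draw <- b["lower", ] + lh[i, ] * (b["upper", ] - b["lower", ])
      names(draw) <- spec$par_names
      if (spec$update_rule == "causal_inference" &&
          draw[["sigma_c2"]] <= draw[["sigma_c1"]] + 0.045)
        draw[["sigma_c2"]] <- draw[["sigma_c1"]] + 0.1
      out <- c(out, list(draw))
    }
  }
  out <- out[seq_len(max(n_starts, min(length(out), n_primary)))]
  attr(out, "n_primary") <- min(n_primary, length(out))
  out
}

moment_start <- function(spec, parts) {
  soas <- parts$soas
  cnt <- parts$pre_counts
  tot <- pmax(rowSums(cnt), 1)
  ps <- cnt[, "S"] / tot
  pss0 <- sum(soas * ps) / max(sum(ps), 1e-9)  # centroid of the S-curve
  width <- diff(range(soas[ps >= 0.5 * max(ps)])) / 2
  b <- spec$bounds
  clamp <- function(name, value)
    min(max(value, b["lower", name] + 1e-6), b["upper", name] - 1e-6)
  st <- c(beta_pre = clamp("beta_pre", -pss0))
  taus <- intersect(c("tau_a", "tau_v", "tau"), spec$par_names)
  for (tn in taus) st[tn] <- clamp(tn, 0.06)
  if (spec$update_rule == "causal_inference")
    st <- c(st, sigma_c1 = clamp("sigma_c1", 0.06),
            sigma_c2 = clamp("sigma_c2", 1), p_common = 0.5)
  # half the empirical S-plateau width overshoots the criterion for
  # causal-inference observers (shrinkage widens the plateau); start midway
  st <- c(st, criterion = clamp("criterion", max(0.6 * width, 0.03)),
          lambda = 0.03,
          alpha = clamp("alpha",
                        if (spec$update_rule == "asynchrony_contingent")
                          0.2 else 0.005))
  st[spec$par_names]
}

#' @export
print.recal_fit <- function(x, ...) {
  cat(sprintf("Recalibration observer-model fit (model %s)\n", x$spec$code))
  cat(sprintf("  trials: %d   sessions: %d   log-likelihood: %.2f\n",
              x$n_obs, length(x$parts$sessions), x$logLik))
  cat("  estimates:\n")
  print(round(x$par, 4))
  invisible(x)
}

#' @export
coef.recal_fit <- function(object, ...) object$par

#' @export
logLik.recal_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$par), nobs = object$n_obs,
            class = "logLik")
}

#' @export
summary.recal_fit <- function(object, ...) {
  ll <- logLik(object)
  structure(list(spec = object$spec, par = object$par,
                 logLik = as.numeric(ll),
                 aic = stats::AIC(ll), bic = stats::BIC(ll),
                 starts = object$starts, best_start = object$best_start,
                 n_obs = object$n_obs),
            class = "summary.recal_fit")
}

#' @export
print.summary.recal_fit <- function(x, ...) {
  cat(sprintf("Model %s: logLik %.2f, AIC %.1f, BIC %.1f (%d trials)\n",
              x$spec$code, x$logLik, x$aic, x$bic, x$n_obs))
  cat("  estimates:\n")
  print(round(x$par, 4))
  cat(sprintf("  best of %d starts (start %d); start log-likelihoods:\n",
              nrow(x$starts), x$best_start))
  print(round(x$starts$loglik, 2))
  invisible(x)
}

#' Predicted psychometric curves of a fitted model
#'
#' Returns the fitted pre-test curve and, per session, the predicted post-test
#' curve evaluated at `beta_pre` plus the mean of the session's simulated
#' cumulative-shift distribution.
#'
#' @param object a [fit_recalibration()] result.
#' @param test_soas SOA grid (defaults to the dataset's grid).
#' @param ... unused.
#' @return A data frame with columns `phase` (`"pre"`/`"post"`), `session`
#'   (`NA` for the shared pre-test curve), `soa` and the three response
#'   probabilities.
#' @export
predict.recal_fit <- function(object, test_soas = NULL, ...) {
  spec <- object$spec
  p <- expand_params(spec, object$par)
  if (is.null(test_soas)) test_soas <- object$parts$soas
  noise <- with_seed(substream_seed(object$rng_seed, 104729), {
    n_tot <- length(object$parts$adapters) * object$control$n_reps *
      object$control$n_exposure
    list(ea = stats::rexp(n_tot), ev = stats::rexp(n_tot))
  })
  finals <- exposure_batch(spec, p, object$parts$adapters,
                           object$control$n_reps, object$control$n_exposure,
                           noise = noise)
  pre <- psychometric_curve(spec, object$par, test_soas)
  out <- cbind(phase = "pre", session = NA_integer_, pre)
  for (i in seq_along(object$parts$sessions)) {
    cur <- psychometric_curve(spec, object$par, test_soas,
                              bias = p$beta_pre + mean(finals[, i]))
    out <- rbind(out, cbind(phase = "post",
                            session = object$parts$sessions[i], cur))
  }
  out
}

#' @export
plot.recal_fit <- function(x, sessions = NULL, ...) {
  pred <- predict(x)
  if (is.null(sessions)) sessions <- x$parts$sessions
  soas <- x$parts$soas
  cols <- c(p_auditory_first = "#3366cc", p_simultaneous = "#33a02c",
            p_visual_first = "#e31a1c")
  old <- graphics::par(mfrow = c(1, min(length(sessions), 3)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in sessions[seq_len(min(length(sessions), 3))]) {
    obs <- x$parts$post_counts[[match(j, x$parts$sessions)]]
    freq <- obs / pmax(rowSums(obs), 1)
    graphics::plot(NA, xlim = range(soas), ylim = c(0, 1),
                   xlab = "test SOA (s)", ylab = "response probability",
                   main = sprintf("session %s (adapter %+0.2f s)", j,
                                  x$parts$adapters[match(j,
                                                         x$parts$sessions)]))
    for (r in seq_along(cols)) {
      cur <- pred[pred$phase == "post" & pred$session %in% j, ]
      graphics::lines(cur$soa, cur[[names(cols)[r]]], col = cols[r])
      prec <- pred[pred$phase == "pre", ]
      graphics::lines(prec$soa, prec[[names(cols)[r]]], col = cols[r],
                      lty = 2)
      graphics::points(soas, freq[, r], col = cols[r], pch = 16, cex = 0.7)
    }
  }
  invisible(x)
}

#' @export
simulate.recal_fit <- function(object, nsim = 1, seed = NULL, ...) {
  design <- experiment_design(adapter_soas = object$parts$adapters)
  obs <- list(spec = object$spec, params = object$par)
  out <- lapply(seq_len(nsim), function(i)
    simulate_experiment(obs, design, rng_seed = substream_seed(seed, i)))
  if (nsim == 1) out[[1]] else out
}

#' Compare fitted observer models
#'
#' Penalized-likelihood comparison of several models fitted to the same
#' dataset: maximized joint log-likelihood, parameter count, AIC and BIC, and
#' differences relative to the weakest model (by BIC), on the half-deviance
#' scale on which approximate log Bayes factors are usually reported.
#'
#' @param ... `"recal_fit"` objects (or a single list of them).
#' @return A data frame of class `"recal_comparison"`, one row per model,
#'   ordered from strongest to weakest.
#' @export
compare_recal_fits <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "recal_fit"))
    fits <- fits[[1]]
  if (length(fits) < 2)
    stop("need at least two fits to compare")
  if (!all(vapply(fits, inherits, logical(1), "recal_fit")))
    stop("all arguments must be 'recal_fit' objects")
  fps <- vapply(fits, function(f) f$data_fingerprint[["checksum"]],
                numeric(1))
  if (length(unique(fps)) != 1)
    stop("fits were obtained on different datasets")
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$code, character(1)),
    n_par = vapply(fits, function(f) length(f$par), integer(1)),
    loglik = vapply(fits, function(f) f$logLik, numeric(1)))
  tab$aic <- -2 * tab$loglik + 2 * tab$n_par
  tab$bic <- -2 * tab$loglik + log(fits[[1]]$n_obs) * tab$n_par
  worst <- which.max(tab$bic)
  tab$d_loglik <- tab$loglik - tab$loglik[worst]
  tab$log_lr_vs_worst <- (tab$bic[worst] - tab$bic) / 2
  tab <- tab[order(tab$bic), ]
  rownames(tab) <- NULL
  class(tab) <- c("recal_comparison", "data.frame")
  tab
}

#' @export
print.recal_comparison <- function(x, ...) {
  cols <- c("model", "n_par", "loglik", "aic", "bic", "d_loglik",
            "log_lr_vs_worst")
  if (!all(cols %in% names(x))) return(NextMethod())
  cat("Observer-model comparison (penalized likelihood; strongest first)\n")
  print.data.frame(cbind(x[, c("model", "n_par")],
                         round(x[, cols[-(1:2)]], 2)))
  invisible(x)
}
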