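desc_par_names <- c("beta_pre", "beta_post", "tau_a", "tau_v", "criterion",
                    "lambda")

desc_bounds <- function() {
  rbind(lower = c(beta_pre = -0.5, beta_post = -0.5, tau_a = 0.005,
                  tau_v = 0.005, criterion = 0.001, lambda = 1e-4),
        upper = c(beta_pre = 0.5, beta_post = 0.5, tau_a = 0.5, tau_v = 0.5,
                  criterion = 0.5, lambda = 0.2))
}

# Closed-form descriptive log-likelihood on sufficient counts.
desc_loglik <- function(par, soas, pre_counts, post_counts) {
  mm <- meas_model(0, par[["tau_a"]], par[["tau_v"]])
  pr_pre <- readout_probs_centred(mm, soas + par[["beta_pre"]],
                                  par[["criterion"]], par[["lambda"]])
  pr_post <- readout_probs_centred(mm, soas + par[["beta_post"]],
                                   par[["criterion"]], par[["lambda"]])
  counts_loglik(pre_counts, pr_pre) + counts_loglik(post_counts, pr_post)
}

readout_probs_centred <- function(mm, centres, criterion, lambda) {
  pv <- 1 - measurement_cdf(mm, criterion - centres)
  pa <- measurement_cdf(mm, -criterion - centres)
  lapse_mix(pa, 1 - pa - pv, pv, lambda)
}

desc_fit_counts <- function(soas, pre_counts, post_counts, start = NULL,
                            n_starts = 3) {
  b <- desc_bounds()
  centroid <- function(cnt) {
    ps <- cnt[, "S"] / pmax(rowSums(cnt), 1)
    sum(soas * ps) / max(sum(ps), 1e-9)
  }
  base <- c(beta_pre = min(max(-centroid(pre_counts), -0.45), 0.45),
            beta_post = min(max(-centroid(post_counts), -0.45), 0.45),
            tau_a = 0.06, tau_v = 0.06, criterion = 0.1, lambda = 0.02)
  starts <- list(base,
                 utils::modifyList(as.list(base),
                                   list(tau_a = 0.03, tau_v = 0.1,
                                        criterion = 0.05)),
                 utils::modifyList(as.list(base),
                                   list(tau_a = 0.1, tau_v = 0.03,
                                        criterion = 0.2)))
  starts <- lapply(starts[seq_len(n_starts)], function(s)
    unlist(s)[desc_par_names])
  if (!is.null(start)) starts <- c(list(start[desc_par_names]), starts)
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, desc_loglik, method = "L-BFGS-B",
                        lower = b["lower", ], upper = b["upper", ],
                        soas = soas, pre_counts = pre_counts,
                        post_counts = post_counts,
                        control = list(fnscale = -1, maxit = 300,
                                       parscale = (b["upper", ] -
                                                     b["lower", ]) / 5))
    if (is.null(best) || opt$value > best$value) best <- opt
  }
  best
}

#' Descriptive joint pre/post psychometric fit of one session
#'
#' Model-agnostic characterisation of recalibration: the ternary
#' measurement-readout psychometric functions are fitted jointly to the pre-
#' and post-test data of one session, with a shared shape (`tau_a`, `tau_v`,
#' `criterion`, `lambda`) and separate biases `beta_pre`, `beta_post` — the
#' curves may shift between tests but not change shape.  Reconstructed from
#' the shared-shape description of the behavioural analysis; fitted by
#' bound-constrained maximum likelihood with closed-form probabilities.
#'
#' @param data trial table; must contain both phases of the session.
#' @param session session to analyse (defaults to the only session present).
#' @return Object of class `"descriptive_fit"`: estimates, log-likelihood,
#'   the session's pre/post PSS (see [pss()]) and recalibration effect.
#' @export
fit_descriptive <- function(data, session = NULL) {
  if (is.null(session)) {
    session <- unique(data$session)
    if (length(session) != 1)
      stop("data contain several sessions; pick one with 'session ='")
  }
  rows <- data[data$session == session, , drop = FALSE]
  for (ph in c("pre", "post"))
    if (!any(rows$phase == ph))
      stop("session ", session, " has no '", ph, "'-phase trials")
  soas <- sort(unique(rows$test_soa_s))
  pre <- counts_by_soa(rows[rows$phase == "pre", , drop = FALSE], soas)
  post <- counts_by_soa(rows[rows$phase == "post", , drop = FALSE], soas)
  opt <- desc_fit_counts(soas, pre, post)
  par <- opt$par
  pss_pre <- pss(par[["tau_a"]], par[["tau_v"]], par[["criterion"]],
                 par[["beta_pre"]])
  pss_post <- pss(par[["tau_a"]], par[["tau_v"]], par[["criterion"]],
                  par[["beta_post"]])
  structure(list(par = par, logLik = opt$value, session = session,
                 soas = soas, pre_counts = pre, post_counts = post,
                 pss_pre = pss_pre, pss_post = pss_post,
                 effect = pss_post - pss_pre),
            class = "descriptive_fit")
}

#' @export
print.descriptive_fit <- function(x, ...) {
  cat(sprintf("Descriptive pre/post fit (session %s): logLik %.2f\n",
              x$session, x$logLik))
  print(round(x$par, 4))
  cat(sprintf("  PSS pre %+.4f s, post %+.4f s, recalibration %+.4f s\n",
              x$pss_pre, x$pss_post, x$effect))
  invisible(x)
}

#' @export
coef.descriptive_fit <- function(object, ...) object$par

#' Point of subjective simultaneity
#'
#' The physical SOA at which the probability of reporting "simultaneous" is
#' maximal, located by a grid search (1-ms steps over ±0.6 s) with local
#' refinement by golden-section search.  The lapse rate rescales the
#' psychometric functions without moving the maximum, so it does not enter.
#' For modality-independent precision (`tau_a = tau_v`) the PSS equals
#' `-bias` exactly.
#'
#' @param tau_a,tau_v arrival-latency time constants (s).
#' @param criterion simultaneity criterion (s).
#' @param bias audiovisual bias of the phase under consideration (s).
#' @return The PSS in seconds.
#' @export
pss <- function(tau_a, tau_v, criterion, bias) {
  mm <- meas_model(0, tau_a, tau_v)
  g <- function(s) {
    centre <- s + bias
    measurement_cdf(mm, criterion - centre) -
      measurement_cdf(mm, -criterion - centre)
  }
  grid <- seq(-0.6, 0.6, by = 0.001)
  i <- which.max(g(grid))
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  stats::optimize(g, lower = lo, upper = hi, maximum = TRUE,
                  tol = 1e-7)$maximum
}

#' Asymmetry index of recalibration
#'
#' Sum of the recalibration effects (post- minus pre-test PSS) across all
#' adapter SOAs.  Zero indicates symmetric recalibration; positive values,
#' greater recalibration for visual-leading adapter SOAs; negative values,
#' greater recalibration for auditory-leading adapter SOAs.
#'
#' @param effects numeric vector of per-session recalibration effects (s).
#' @return The index in seconds.
#' @export
asymmetry_index <- function(effects) sum(effects)

#' Model-agnostic recalibration summary with bootstrap confidence intervals
#'
#' Fits the descriptive shifted-curve model ([fit_descriptive()]) to every
#' session, extracts pre/post PSS and the per-session recalibration effect,
#' and sums the effects into the asymmetry index.  Uncertainty is assessed by
#' a nonparametric bootstrap: responses are resampled with replacement within
#' each (session, phase, test SOA) cell — preserving the design — the fits are
#' repeated, and percentile intervals are reported.
#'
#' @param data full trial table (all sessions, both phases).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param rng_seed optional seed.
#' @return Object of class `"recal_summary"`: `sessions` (data frame with
#'   per-session adapter SOA, PSS and effect estimates plus CIs), `asymmetry`
#'   (index with CI), `n_boot`.
#' @export
analyze_recalibration <- function(data, n_boot = 1000, conf = 0.95,
                                  rng_seed = NULL) {
  sessions <- sort(unique(data$session))
  no_pre <- sessions[!sessions %in% data$session[data$phase == "pre"]]
  no_post <- sessions[!sessions %in% data$session[data$phase == "post"]]
  if (length(no_pre) || length(no_post))
    stop("session(s) missing a phase: ",
         paste(unique(c(no_pre, no_post)), collapse = ", "))
  fits <- lapply(sessions, function(j) fit_descriptive(data, session = j))
  adapters <- vapply(sessions, function(j)
    unique(data$adapter_soa_s[data$session == j])[1], numeric(1))
  effects <- vapply(fits, `[[`, numeric(1), "effect")

  boot_eff <- NULL
  if (n_boot > 0) {
    boot_eff <- matrix(NA_real_, n_boot, length(sessions))
    for (b in seq_len(n_boot)) {
      for (i in seq_along(sessions)) {
        f <- fits[[i]]
        bp <- resample_counts(f$pre_counts,
                              substream_seed(rng_seed, b, i, 1))
        bq <- resample_counts(f$post_counts,
                              substream_seed(rng_seed, b, i, 2))
        opt <- desc_fit_counts(f$soas, bp, bq, start = f$par, n_starts = 1)
        boot_eff[b, i] <-
          pss(opt$par[["tau_a"]], opt$par[["tau_v"]],
              opt$par[["criterion"]], opt$par[["beta_post"]]) -
          pss(opt$par[["tau_a"]], opt$par[["tau_v"]],
              opt$par[["criterion"]], opt$par[["beta_pre"]])
      }
    }
  }
  alpha2 <- (1 - conf) / 2
  ci <- function(x) stats::quantile(x, c(alpha2, 1 - alpha2), names = FALSE)
  eff_ci <- if (is.null(boot_eff)) matrix(NA_real_, length(sessions), 2)
            else t(apply(boot_eff, 2, ci))
  idx_ci <- if (is.null(boot_eff)) c(NA_real_, NA_real_)
            else ci(rowSums(boot_eff))
  out <- list(
    sessions = data.frame(session = sessions, adapter_soa_s = adapters,
                          pss_pre = vapply(fits, `[[`, numeric(1),
                                           "pss_pre"),
                          pss_post = vapply(fits, `[[`, numeric(1),
                                            "pss_post"),
                          effect = effects,
                          ci_lower = eff_ci[, 1], ci_upper = eff_ci[, 2]),
    asymmetry = c(index = asymmetry_index(effects),
                  ci_lower = idx_ci[1], ci_upper = idx_ci[2]),
    conf = conf, n_boot = n_boot, fits = fits)
  class(out) <- "recal_summary"
  out
}

# Multinomial resample of each test-SOA row of a count matrix.
resample_counts <- function(counts, seed) {
  with_seed(seed, {
    out <- counts
    for (r in seq_len(nrow(counts))) {
      n <- sum(counts[r, ])
      if (n > 0)
        out[r, ] <- as.numeric(stats::rmultinom(1, n, counts[r, ] / n))
    }
    out
  })
}

#' @export
print.recal_summary <- function(x, ...) {
  cat("Recalibration summary (descriptive shifted-curve fits)\n")
  print(cbind(x$sessions[, 1:2], round(x$sessions[, -(1:2)], 4)))
  cat(sprintf("Asymmetry index: %+.4f s [%0.4f, %0.4f] (%d%% bootstrap, %d resamples)\n",
              x$asymmetry[["index"]], x$asymmetry[["ci_lower"]],
              x$asymmetry[["ci_upper"]], round(100 * x$conf), x$n_boot))
  invisible(x)
}

#' @export
plot.recal_summary <- function(x, ...) {
  s <- x$sessions[order(x$sessions$adapter_soa_s), ]
  graphics::plot(s$adapter_soa_s, s$effect, type = "b", pch = 16,
                 xlab = "adapter SOA (s)", ylab = "recalibration effect (s)",
                 main = "PSS shift vs adapter SOA")
  if (all(is.finite(s$ci_lower)))
    graphics::arrows(s$adapter_soa_s, s$ci_lower, s$adapter_soa_s,
                     s$ci_upper, angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
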