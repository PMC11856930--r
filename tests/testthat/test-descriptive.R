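# Build one session of readout-observer data with separate pre/post biases.
session_data <- function(beta_pre, beta_post, tau_a = 0.06, tau_v = 0.08,
                         criterion = 0.1, lambda = 0.02, n_rep = 20,
                         session = 1, adapter = 0.2, seed = 1) {
  soas <- experiment_design()$test_soas
  mm_pre <- meas_model(beta_pre, tau_a, tau_v)
  mm_post <- meas_model(beta_post, tau_a, tau_v)
  rbind(sample_phase_data(toj_probs_readout(mm_pre, soas, criterion, lambda),
                          soas, n_rep, session, "pre", adapter, seed),
        sample_phase_data(toj_probs_readout(mm_post, soas, criterion, lambda),
                          soas, n_rep, session, "post", adapter, seed + 1))
}

test_that("the descriptive fit recovers the pre/post biases", {
  # recovery error at 300 trials/phase is sampling-noise limited, so assert
  # the typical (median) error over a few replicate datasets
  errs <- vapply(1:9, function(k) {
    dat <- session_data(beta_pre = -0.02, beta_post = -0.05, seed = 10 * k)
    fit <- fit_descriptive(dat)
    c(abs(fit$par[["beta_pre"]] + 0.02), abs(fit$par[["beta_post"]] + 0.05))
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.015)
  expect_lt(median(errs[2, ]), 0.02)
  fit <- fit_descriptive(session_data(-0.02, -0.05, seed = 10))
  expect_equal(fit$effect, fit$pss_post - fit$pss_pre)
})

test_that("identical pre and post data give matching biases and the fit is
           order-invariant", {
  dat <- session_data(beta_pre = -0.03, beta_post = -0.03, seed = 21)
  dat$response[dat$phase == "post"] <- dat$response[dat$phase == "pre"]
  dat$test_soa_s[dat$phase == "post"] <- dat$test_soa_s[dat$phase == "pre"]
  fit <- fit_descriptive(dat)
  expect_lt(abs(fit$par[["beta_pre"]] - fit$par[["beta_post"]]), 2e-3)
  set.seed(1)
  fit2 <- fit_descriptive(dat[sample.int(nrow(dat)), ])
  expect_equal(fit$par, fit2$par, tolerance = 1e-8)
  expect_error(fit_descriptive(dat[dat$phase == "pre", ]), "no 'post'")
})

test_that("the PSS equals minus the bias under symmetric precision and is
           found by grid search plus refinement", {
  expect_equal(pss(0.06, 0.06, criterion = 0.08, bias = -0.04), 0.04,
               tolerance = 1e-6)
  expect_equal(pss(0.06, 0.06, criterion = 0.2, bias = 0.1), -0.1,
               tolerance = 1e-6)
  # asymmetric precision: refined value matches a brute-force fine grid
  mm <- meas_model(0, 0.04, 0.11)
  g <- function(s) measurement_cdf(mm, 0.09, s + 0.03) -
    measurement_cdf(mm, -0.09, s + 0.03)
  grid <- seq(-0.6, 0.6, by = 1e-4)
  expect_lt(abs(pss(0.04, 0.11, 0.09, 0.03) - grid[which.max(g(grid))]),
            1e-4)
})

test_that("the asymmetry index sums session effects with the stated sign
           convention", {
  eff <- c(-0.05, -0.03, -0.02, -0.01, 0, 0.01, 0.02, 0.03, 0.05)
  expect_equal(asymmetry_index(eff), 0)          # antisymmetric
  expect_equal(asymmetry_index(eff + 0.01), 0.09)  # linear in a common shift
  expect_gt(asymmetry_index(c(eff[1:5], 2 * eff[6:9])), 0)  # visual-lead bias
})

test_that("analyze_recalibration summarises sessions and bootstraps the
           asymmetry index", {
  # a negative (auditory-lead) adapter increases the bias, lowering the PSS;
  # a positive adapter decreases it
  dats <- rbind(
    session_data(-0.02, 0.03, session = 1, adapter = -0.3, seed = 31),
    session_data(-0.02, -0.02, session = 2, adapter = 0, seed = 41),
    session_data(-0.02, -0.07, session = 3, adapter = 0.3, seed = 51))
  sm <- analyze_recalibration(dats, n_boot = 60, rng_seed = 9)
  expect_equal(nrow(sm$sessions), 3)
  expect_equal(sm$sessions$effect,
               sm$sessions$pss_post - sm$sessions$pss_pre)
  expect_equal(sm$asymmetry[["index"]], sum(sm$sessions$effect))
  expect_true(all(sm$sessions$ci_lower <= sm$sessions$effect + 1e-9))
  expect_true(all(sm$sessions$ci_upper >= sm$sessions$effect - 1e-9))
  # recalibration toward the adapter: negative adapter shifts the PSS down
  expect_lt(sm$sessions$effect[1], 0)
  expect_gt(sm$sessions$effect[3], 0)
  # reproducible given the seed
  sm2 <- analyze_recalibration(dats, n_boot = 60, rng_seed = 9)
  expect_identical(sm$asymmetry, sm2$asymmetry)
  # a session missing a phase is reported
  expect_error(analyze_recalibration(dats[!(dats$session == 2 &
                                              dats$phase == "post"), ],
                                     n_boot = 0), "missing a phase: 2")
})

test_that("bootstrap intervals narrow with more trials per cell", {
  d20 <- rbind(session_data(-0.02, -0.05, n_rep = 20, seed = 61),
               session_data(-0.02, -0.05, n_rep = 20, session = 2,
                            adapter = 0.1, seed = 71))
  d80 <- rbind(session_data(-0.02, -0.05, n_rep = 80, seed = 81),
               session_data(-0.02, -0.05, n_rep = 80, session = 2,
                            adapter = 0.1, seed = 91))
  w <- function(d) {
    sm <- analyze_recalibration(d, n_boot = 60, rng_seed = 5)
    unname(sm$asymmetry[["ci_upper"]] - sm$asymmetry[["ci_lower"]])
  }
  ratio <- w(d80) / w(d20)
  expect_lt(ratio, 0.85)   # roughly 1/sqrt(4) = 0.5, allow slack
  expect_gt(ratio, 0.2)
})
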