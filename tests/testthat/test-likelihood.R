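make_ci_dataset <- function(seed = 1, params = ci_ms_params()) {
  obs <- list(spec = recal_model("ci_ms"), params = params)
  simulate_experiment(obs, rng_seed = seed)
}

test_that("the pre-test log-likelihood is the response-weighted sum of log
           psychometric probabilities", {
  spec <- recal_model("ac_ms")
  pars <- ac_ms_params()
  p <- avrecal:::expand_params(spec, pars)
  mm <- meas_model(p$beta_pre, p$tau_a, p$tau_v)
  one <- data.frame(test_soa_s = 0.1, response = "A")
  pr <- toj_probs_readout(mm, 0.1, p$criterion, p$lambda)
  expect_equal(pretest_loglik(one, spec, pars),
               log(pr[, "p_auditory_first"]), ignore_attr = TRUE)
  # additivity: duplicating the records doubles the log-likelihood
  soas <- seq(-0.3, 0.3, by = 0.1)
  dat <- sample_phase_data(toj_probs_readout(mm, soas, p$criterion,
                                             p$lambda), soas, 10, seed = 2)
  expect_equal(pretest_loglik(rbind(dat, dat), spec, pars),
               2 * pretest_loglik(dat, spec, pars))
})

test_that("the aggregated likelihood matches a naive per-trial loop", {
  spec <- recal_model("ci_ms")
  pars <- ci_ms_params()
  p <- avrecal:::expand_params(spec, pars)
  mm <- meas_model(p$beta_pre, p$tau_a, p$tau_v)
  prior <- causal_prior(pars["sigma_c1"], pars["sigma_c2"],
                        pars["p_common"])
  soas <- c(-0.5, -0.2, 0, 0.15, 0.4)
  probs <- toj_probs_ci_exact(mm, soas, p$criterion, p$lambda, prior)
  dat <- sample_phase_data(probs, soas, 20, seed = 3)
  loop <- 0
  for (k in seq_len(nrow(dat))) {
    i <- match(dat$test_soa_s[k], soas)
    r <- match(dat$response[k], c("A", "S", "V"))
    loop <- loop + log(probs[i, r])
  }
  expect_equal(pretest_loglik(dat, spec, pars), loop, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("log-likelihoods are invariant to trial order", {
  dat <- make_ci_dataset(seed = 5)
  spec <- recal_model("ci_ms")
  set.seed(6)
  shuffled <- dat[sample.int(nrow(dat)), ]
  expect_equal(joint_loglik(dat, spec, ci_ms_params(), rng_seed = 1,
                            n_reps = 100),
               joint_loglik(shuffled, spec, ci_ms_params(), rng_seed = 1,
                            n_reps = 100), ignore_attr = TRUE)
})

test_that("with no recalibration the post-test term equals the pre-test
           likelihood of the post-test records", {
  pars0 <- ci_ms_params(alpha = 0)
  spec <- recal_model("ci_ms")
  dat <- make_ci_dataset(seed = 7, params = pars0)
  post <- dat[dat$phase == "post", ]
  dists <- lapply(1:9, function(j)
    approximate_shift_distribution(spec, pars0, 0.1, n_reps = 50,
                                   rng_seed = j))
  expect_lt(abs(posttest_loglik(post, spec, pars0, dists) -
                  pretest_loglik(post, spec, pars0)), 1e-9)
})

test_that("a single-bin shift distribution reduces to the shifted-curve
           product", {
  spec <- recal_model("ac_mi")
  pars <- c(beta_pre = -0.02, tau = 0.07, criterion = 0.1, lambda = 0.02,
            alpha = 0.3)
  p <- avrecal:::expand_params(spec, pars)
  delta <- -0.04
  pm <- structure(list(mean = delta, sd = 0, bin_centers = delta,
                       bin_weights = 1, lower = delta, upper = delta,
                       bin_width = 0, sample_range = c(delta, delta),
                       point_mass = TRUE, n_reps = 10),
                  class = "shift_distribution")
  soas <- c(-0.2, 0, 0.2)
  mm <- meas_model(p$beta_pre + delta, p$tau_a, p$tau_v)
  probs <- toj_probs_readout(mm, soas, p$criterion, p$lambda)
  dat <- sample_phase_data(probs, soas, 15, phase = "post", seed = 8)
  direct <- 0
  for (k in seq_len(nrow(dat))) {
    i <- match(dat$test_soa_s[k], soas)
    r <- match(dat$response[k], c("A", "S", "V"))
    direct <- direct + log(probs[i, r])
  }
  expect_equal(posttest_loglik(dat, spec, pars, list(pm)), direct,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the binned integral is converged at 100 bins", {
  spec <- recal_model("ci_ms")
  pars <- ci_ms_params()
  obs <- list(spec = spec, params = pars)
  design <- experiment_design(adapter_soas = 0.2)
  dat <- simulate_experiment(obs, design, rng_seed = 9)   # 300 post trials
  post <- dat[dat$phase == "post", ]
  p <- avrecal:::expand_params(spec, pars)
  finals <- avrecal:::exposure_batch(spec, p, 0.2, 500, 250, rng_seed = 10)
  d100 <- avrecal:::shift_distribution_from_sample(finals[, 1], 100)
  d1000 <- avrecal:::shift_distribution_from_sample(finals[, 1], 1000)
  ll100 <- posttest_loglik(post, spec, pars, list(d100))
  ll1000 <- posttest_loglik(post, spec, pars, list(d1000))
  expect_lt(abs(ll100 - ll1000), 0.01)
})

test_that("the joint likelihood decomposes and is seed-deterministic", {
  dat <- make_ci_dataset(seed = 11)
  spec <- recal_model("ci_ms")
  ll1 <- joint_loglik(dat, spec, ci_ms_params(), rng_seed = 4, n_reps = 100)
  ll2 <- joint_loglik(dat, spec, ci_ms_params(), rng_seed = 4, n_reps = 100)
  expect_identical(as.numeric(ll1), as.numeric(ll2))
  expect_equal(as.numeric(ll1), attr(ll1, "pre") + attr(ll1, "post"))
})

test_that("the generating parameters dominate random perturbations", {
  pars <- ci_ms_params()
  spec <- recal_model("ci_ms")
  dat <- make_ci_dataset(seed = 13, params = pars)
  ll_true <- joint_loglik(dat, spec, pars, rng_seed = 3, n_reps = 1000)
  set.seed(14)
  wins <- 0
  for (k in 1:20) {
    pert <- pars * (1 + 0.05 * sample(c(-1, 1), length(pars), TRUE))
    pert["p_common"] <- min(pert[["p_common"]], 1)
    ll_p <- joint_loglik(dat, spec, pert, rng_seed = 3, n_reps = 1000)
    if (ll_true > ll_p) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("malformed datasets are rejected with informative errors", {
  dat <- make_ci_dataset(seed = 15)
  spec <- recal_model("ci_ms")
  expect_error(joint_loglik(dat[, -3], spec, ci_ms_params(), rng_seed = 1),
               "adapter_soa_s")
  bad <- dat
  bad$adapter_soa_s[5] <- 99
  expect_error(joint_loglik(bad, spec, ci_ms_params(), rng_seed = 1),
               "non-constant")
  expect_error(posttest_loglik(dat[dat$phase == "post", ], spec,
                               ci_ms_params(), list()), "per session")
})
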