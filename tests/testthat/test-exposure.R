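test_that("a zero learning rate leaves the bias untouched for every rule", {
  for (setup in list(list("ci_ms", ci_ms_params(alpha = 0)),
                     list("ac_ms", ac_ms_params(alpha = 0)),
                     list("corr_mi", corr_mi_params(alpha = 0)))) {
    spec <- recal_model(setup[[1]])
    traj <- simulate_exposure(spec, setup[[2]], adapter_soa = 0.3,
                              rng_seed = 1)
    expect_identical(as.numeric(traj), rep(0, 251))
  }
})

test_that("trajectories have the design length, start at zero, and are
           seed-reproducible", {
  spec <- recal_model("ci_ms")
  t1 <- simulate_exposure(spec, ci_ms_params(), 0.2, rng_seed = 3)
  t2 <- simulate_exposure(spec, ci_ms_params(), 0.2, rng_seed = 3)
  expect_length(t1, 251)
  expect_identical(t1[1], 0)
  expect_identical(as.numeric(t1), as.numeric(t2))
  t3 <- simulate_exposure(spec, ci_ms_params(), 0.2, n_trials = 40,
                          rng_seed = 1)
  expect_length(t3, 41)
})

test_that("the pure-R trajectory and the batch kernel agree statistically", {
  spec <- recal_model("corr_mi")
  pars <- corr_mi_params(alpha = 0.02)
  finals_r <- vapply(1:300, function(i)
    unclass(simulate_exposure(spec, pars, 0.3, rng_seed = 1000 + i))[251],
    numeric(1))
  dist_c <- approximate_shift_distribution(spec, pars, 0.3, n_reps = 3000,
                                           rng_seed = 7)
  se <- sd(finals_r) / sqrt(300)
  expect_lt(abs(mean(finals_r) - dist_c$mean), 4 * se)
})

test_that("the causal-inference batch kernel reproduces the exact update
           within interpolation error", {
  spec <- recal_model("ci_ms")
  pars <- ci_ms_params()
  p <- avrecal:::expand_params(spec, pars)
  set.seed(5)
  n_tr <- 250
  noise <- list(ea = rexp(n_tr), ev = rexp(n_tr))
  # exact R recursion with the same deviates
  prior <- causal_prior(pars["sigma_c1"], pars["sigma_c2"], pars["p_common"])
  delta <- 0
  for (i in seq_len(n_tr)) {
    m <- 0.3 + p$beta_pre + delta + p$tau_a * noise$ea[i] -
      p$tau_v * noise$ev[i]
    est <- avrecal:::ci_estimate_u(m, p$tau_a, p$tau_v, prior)
    delta <- delta + p$alpha * (est - m)
  }
  kern <- avrecal:::exposure_batch(spec, p, 0.3, n_reps = 1, n_trials = n_tr,
                                   noise = noise)
  expect_lt(abs(kern[1, 1] - delta), 1e-4)
})

test_that("full attribution with a tight common-cause prior drives the bias
           to cancel the adapter SOA", {
  spec <- recal_model("ci_mi")
  pars <- ci_mi_params(beta_pre = 0.02, tau = 0.06, sigma_c1 = 0.002,
                       p_common = 1, alpha = 0.01)
  for (adapter in c(0.3, -0.25)) {
    dist <- approximate_shift_distribution(spec, pars, adapter,
                                           n_reps = 1000, rng_seed = 11)
    target <- -(adapter + 0.02) * (1 - (1 - 0.01)^250)
    expect_lt(abs(dist$mean - target) / abs(target), 0.05)
  }
})

test_that("a compensated adapter with symmetric noise produces no net shift", {
  spec <- recal_model("ci_mi")
  pars <- ci_mi_params(beta_pre = 0.05, tau = 0.06)
  dist <- approximate_shift_distribution(spec, pars, adapter_soa = -0.05,
                                         n_reps = 2000, rng_seed = 13)
  expect_lt(abs(dist$mean), 3 * dist$sd / sqrt(2000) + 1e-4)
})

test_that("shift distributions follow the printed binning recipe", {
  spec <- recal_model("ci_ms")
  d <- approximate_shift_distribution(spec, ci_ms_params(), 0.2,
                                      n_reps = 400, rng_seed = 3)
  expect_length(d$bin_centers, 100)
  rng <- d$sample_range
  expect_equal(d$lower, rng[1] - (rng[2] - rng[1]))
  expect_equal(d$upper, rng[2] + (rng[2] - rng[1]))
  expect_equal(diff(d$bin_centers), rep(d$bin_width, 99))
  expect_equal(d$bin_centers[1], d$lower + d$bin_width / 2)
  expect_true(all(d$bin_weights >= 0))
  # Riemann mass approximates the Gaussian mass over [lower, upper]
  mass <- sum(d$bin_weights) * d$bin_width
  expect_equal(mass, pnorm(d$upper, d$mean, d$sd) -
                 pnorm(d$lower, d$mean, d$sd), tolerance = 1e-3)
  # the reported mean is the arithmetic mean of the simulated final shifts
  p <- avrecal:::expand_params(spec, ci_ms_params())
  finals <- avrecal:::exposure_batch(spec, p, 0.2, 400, 250, rng_seed = 3)
  expect_equal(d$mean, mean(finals[, 1]))
})

test_that("degenerate dynamics give a point-mass shift distribution", {
  spec <- recal_model("corr_mi")
  d <- approximate_shift_distribution(spec, corr_mi_params(alpha = 0), 0.3,
                                      n_reps = 50, rng_seed = 1)
  expect_true(d$point_mass)
  expect_identical(d$mean, 0)
  expect_identical(d$sd, 0)
  expect_identical(d$bin_weights, 1)
})

test_that("the posterior-weighted variant updates only through the common-cause
           posterior", {
  spec <- recal_model("ci_ms")
  pars <- ci_ms_params(p_common = 0)
  traj <- simulate_exposure(spec, pars, 0.3, n_trials = 50, rng_seed = 2,
                            variant = "posterior")
  expect_identical(as.numeric(traj), rep(0, 51))  # posterior is always zero
  traj2 <- simulate_exposure(spec, ci_ms_params(), 0.3, n_trials = 50,
                             rng_seed = 2, variant = "posterior")
  expect_false(all(traj2 == 0))
  expect_error(simulate_exposure(recal_model("ac_ms"), ac_ms_params(), 0.3,
                                 variant = "posterior"), "causal-inference")
})

test_that("contingent recalibration collapses at large adapter SOAs while the
           causal-inference shift persists", {
  spec_ac <- recal_model("ac_mi")
  pars_ac <- c(beta_pre = 0, tau = 0.06, criterion = 0.08, lambda = 0.02,
               alpha = 0.15)
  m_02 <- approximate_shift_distribution(spec_ac, pars_ac, 0.2,
                                         n_reps = 800, rng_seed = 5)$mean
  m_07 <- approximate_shift_distribution(spec_ac, pars_ac, 0.7,
                                         n_reps = 800, rng_seed = 5)$mean
  expect_lt(abs(m_07), 0.1 * abs(m_02))
  spec_ci <- recal_model("ci_mi")
  pars_ci <- ci_mi_params(beta_pre = 0, tau = 0.07, p_common = 0.9)
  d7 <- approximate_shift_distribution(spec_ci, pars_ci, 0.7,
                                       n_reps = 800, rng_seed = 5)
  expect_gt(abs(d7$mean), 3 * d7$sd / sqrt(800))
})

test_that("latency-precision differences make recalibration asymmetric", {
  spec <- recal_model("ci_ms")
  shift_at <- function(pars, adapter)
    approximate_shift_distribution(spec, pars, adapter, n_reps = 800,
                                   rng_seed = 9)$mean
  sharp_audition <- ci_ms_params(beta_pre = 0, tau_a = 0.03, tau_v = 0.1)
  expect_gt(abs(shift_at(sharp_audition, -0.3)),
            abs(shift_at(sharp_audition, 0.3)))
  sharp_vision <- ci_ms_params(beta_pre = 0, tau_a = 0.1, tau_v = 0.03)
  expect_lt(abs(shift_at(sharp_vision, -0.3)),
            abs(shift_at(sharp_vision, 0.3)))
})
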