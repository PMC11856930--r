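# Dense-grid search over the scenario-conditioned log-posterior; the
# brute-force oracle for the closed-form three-candidate MAP estimate.
grid_map_oracle <- function(model, m, sigma, lim = 1.5, step = 1e-5) {
  s <- seq(-lim, lim, by = step)
  lp <- log(measurement_density(model, m, s)) + dnorm(s, 0, sigma, log = TRUE)
  s[which.max(lp)]
}

test_that("closed-form MAP equals the dense-grid argmax", {
  obs <- meas_model(0, 0.06, 0.07)
  expect_lt(abs(conditional_map_estimate(obs, 0.2, 0.1) -
                  grid_map_oracle(obs, 0.2, 0.1)), 1e-4)
  set.seed(21)
  for (i in 1:40) {
    obs <- meas_model(runif(1, -0.1, 0.1), runif(1, 0.02, 0.2),
                      runif(1, 0.02, 0.2))
    m <- runif(1, -0.6, 0.6)
    sigma <- runif(1, 0.02, 0.5)
    expect_lt(abs(conditional_map_estimate(obs, m, sigma) -
                    grid_map_oracle(obs, m, sigma)), 1e-4)
  }
})

test_that("MAP limits: flat prior returns m - bias, tight prior returns 0", {
  obs <- meas_model(0.02, 0.06, 0.07)
  expect_equal(conditional_map_estimate(obs, 0.15, 50), 0.15 - 0.02)
  expect_equal(conditional_map_estimate(obs, 0.15, 1e-5), 0,
               tolerance = 1e-6)
  expect_error(conditional_map_estimate(obs, 0.1, 0), "positive")
})

test_that("posterior of a common cause obeys its analytic limits", {
  obs <- meas_model(0, 0.06, 0.07)
  m <- c(-0.4, 0, 0.25)
  expect_equal(posterior_common_cause(obs, m, causal_prior(0.05, 1, 1)),
               rep(1, 3))
  expect_equal(posterior_common_cause(obs, m, causal_prior(0.05, 1, 0)),
               rep(0, 3))
  # identical spreads make the scenario likelihoods cancel
  for (pc in c(0.2, 0.5, 0.9))
    expect_equal(posterior_common_cause(obs, m, causal_prior(0.3, 0.3, pc)),
                 rep(pc, 3), tolerance = 1e-12)
})

test_that("closed-form scenario likelihoods match quadrature", {
  set.seed(31)
  for (i in 1:25) {
    obs <- meas_model(runif(1, -0.1, 0.1), runif(1, 0.02, 0.15),
                      runif(1, 0.02, 0.15))
    m <- runif(1, -0.8, 0.8)
    sigma <- runif(1, 0.01, 1.5)
    quad <- stats::integrate(function(s)
      measurement_density(obs, m, s) * dnorm(s, 0, sigma),
      -Inf, Inf, rel.tol = 1e-11)$value
    closed <- exp(avrecal:::log_scenario_lik(m - obs$bias, obs$tau_a,
                                             obs$tau_v, sigma))
    expect_lt(abs(closed / quad - 1), 1e-4)
  }
})

test_that("posterior of a common cause decreases with measured asynchrony", {
  obs <- meas_model(0.02, 0.06, 0.08)
  prior <- causal_prior(0.03, 1.2, 0.6)
  m <- obs$bias + seq(0, 1, by = 0.02)    # growing |m - bias|
  expect_true(all(diff(posterior_common_cause(obs, m, prior)) <= 1e-12))
  m2 <- obs$bias - seq(0, 1, by = 0.02)
  expect_true(all(diff(posterior_common_cause(obs, m2, prior)) <= 1e-12))
})

test_that("model averaging interpolates between the conditional MAPs", {
  obs <- meas_model(-0.01, 0.05, 0.09)
  set.seed(41)
  for (i in 1:100) {
    prior <- causal_prior(runif(1, 0.01, 0.2), runif(1, 0.3, 2), runif(1))
    m <- runif(1, -0.8, 0.8)
    r <- infer_soa(obs, m, prior)
    expect_gte(r$estimate, min(r$map_c1, r$map_c2) - 1e-12)
    expect_lte(r$estimate, max(r$map_c1, r$map_c2) + 1e-12)
    expect_true(r$posterior_c1 >= 0 && r$posterior_c1 <= 1)
    # shrinkage: the estimate never exceeds the flat-prior percept
    expect_lte(abs(r$estimate), abs(m - obs$bias) + 1e-12)
  }
  # pc = 1 / pc = 0 collapse onto the conditional estimates
  r1 <- infer_soa(obs, 0.3, causal_prior(0.05, 1, 1))
  expect_equal(r1$estimate, r1$map_c1)
  r0 <- infer_soa(obs, 0.3, causal_prior(0.05, 1, 0))
  expect_equal(r0$estimate, r0$map_c2)
})

test_that("the estimate moves monotonically with the common-cause prior", {
  obs <- meas_model(0, 0.06, 0.07)
  pcs <- seq(0, 1, by = 0.05)
  est <- vapply(pcs, function(pc)
    infer_soa(obs, 0.3, causal_prior(0.04, 1, pc))$estimate, numeric(1))
  expect_true(all(diff(est) <= 1e-12))  # moves from map_c2 toward map_c1
})

test_that("bias-update rules implement the printed arithmetic", {
  expect_equal(ci_bias_update(0, m = 0.25, estimate = 0.10, alpha = 0.01),
               -0.0015)
  expect_equal(ci_bias_update(0.02, m = 0.1, estimate = 0.1, alpha = 0.05),
               0.02)
  expect_equal(ci_bias_update(0.02, m = 0.1, estimate = 0.05, alpha = 0),
               0.02)
  expect_error(ci_bias_update(0, 0.1, 0.1, -0.1), "non-negative")
  # posterior-weighted variant
  expect_equal(ci_bias_update_posterior_variant(0, m = 0.2,
                                                posterior_c1 = 0.5,
                                                alpha = 0.01), -0.001)
  expect_equal(ci_bias_update_posterior_variant(0.01, 0.2, 0, 0.05), 0.01)
  expect_equal(ci_bias_update_posterior_variant(0.01, 0.2, 0.7, 0), 0.01)
})

test_that("degenerate causal priors are rejected", {
  expect_error(causal_prior(0.2, 0.1, 0.5), "smaller")
  expect_error(causal_prior(-0.1, 1, 0.5), "positive")
  expect_error(causal_prior(0.05, 1, 1.2), "0, 1")
})
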