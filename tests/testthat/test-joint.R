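joint_fit_cache <- new.env()

small_joint_fit <- function() {
  if (is.null(joint_fit_cache$fit)) {
    u <- joint_universe()
    joint_fit_cache$fit <- suppressWarnings(
      fit_joint(u$samples, u$areas, u$edges, "observed_men", "expected_men",
                joint_spec(), mcmc_config(n_iter = 500, burnin = 250,
                                          seed = 77)))
  }
  joint_fit_cache$fit
}

test_that("the joint model recovers the exposure effect and field hyperparameters", {
  u <- joint_universe()
  fit <- small_joint_fit()
  rr <- fit$rr_table
  expect_equal(rr$parameter, "rr_log")
  # truth: RR 1.2 per unit log concentration
  expect_gt(rr$q97.5, 1.2 * 0.98)
  expect_lt(rr$q2.5, 1.2 * 1.02)
  expect_gt(rr$mean, 1.05)
  fs <- fit$field_summary
  # generating values: range 20 km, sigma_f 0.7, sigma_x 0.45, mu_x log 9
  expect_lt(abs(fs$mean[fs$parameter == "range"] / 20 - 1), 0.5)
  expect_lt(abs(fs$mean[fs$parameter == "sigma_f"] / 0.7 - 1), 0.5)
  expect_lt(abs(fs$mean[fs$parameter == "sigma_x"] / 0.45 - 1), 0.25)
  expect_lt(abs(fs$mean[fs$parameter == "mu_x"] - log(9)), 0.8)
})

test_that("joint fits are reproducible by seed", {
  u <- joint_universe()
  mc <- mcmc_config(n_iter = 60, burnin = 40, seed = 5)
  f1 <- suppressWarnings(fit_joint(u$samples, u$areas, u$edges,
                                   "observed_men", "expected_men",
                                   joint_spec(), mc))
  f2 <- suppressWarnings(fit_joint(u$samples, u$areas, u$edges,
                                   "observed_men", "expected_men",
                                   joint_spec(), mc))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$field_draws, f2$field_draws)
})

test_that("field posterior projection is exact at vertices and tighter where sampled", {
  fit <- small_joint_fit()
  u <- joint_universe()
  mesh <- fit$mesh
  # at a mesh vertex the projection equals the vertex-weight summary exactly
  centre <- which.min(rowSums((mesh$vertices - 30)^2))
  fp <- field_posterior_at(mesh$vertices[centre, , drop = FALSE], fit)
  draws <- fit$field_draws[, 1] + fit$field_draws[, 1 + centre]
  expect_equal(fp$mean, mean(draws), tolerance = 1e-12)
  expect_equal(fp$sd, sd(draws), tolerance = 1e-12)
  # at a densely sampled location the posterior SD is below the prior
  # marginal SD of the field
  dense_pt <- u$samples[which.max(u$samples$x_km < 20), c("x_km", "y_km")]
  fp2 <- field_posterior_at(as.matrix(dense_pt), fit)
  prior_sd <- fit$field_summary$mean[fit$field_summary$parameter == "sigma_f"]
  expect_lt(fp2$sd, prior_sd)
  # points off the mesh are flagged
  expect_warning(out <- field_posterior_at(matrix(c(1e4, 1e4), 1), fit),
                 "outside")
  expect_true(is.na(out$mean))
})

test_that("predictive intervals for held-out samples have near-nominal coverage", {
  u <- joint_universe()
  set.seed(55)
  hold <- sample(nrow(u$samples), 80)
  fit <- suppressWarnings(
    fit_joint(u$samples[-hold, ], u$areas, u$edges, "observed_men",
              "expected_men", joint_spec(),
              mcmc_config(n_iter = 400, burnin = 200, seed = 31)))
  fp <- field_posterior_at(u$samples[hold, c("x_km", "y_km")], fit)
  sx <- fit$field_summary$mean[fit$field_summary$parameter == "sigma_x"]
  lo <- fp$mean + qnorm(0.025) * sqrt(fp$sd^2 + sx^2)
  hi <- fp$mean + qnorm(0.975) * sqrt(fp$sd^2 + sx^2)
  y <- u$samples$log_concentration[hold]
  cov <- mean(y >= lo & y <= hi)
  expect_gte(cov, 0.88)
  expect_lte(cov, 0.99)
})
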