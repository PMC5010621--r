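test_that("identical groups give a difference straddling zero", {
  set.seed(1)
  g <- rnorm(200, 10, 2)
  d <- diff_of_means(g, g, seed = 4)
  expect_lt(abs(d$mean), 0.2)
  expect_lt(d$q2.5, 0)
  expect_gt(d$q97.5, 0)
})

test_that("an elementwise shift is recovered", {
  set.seed(2)
  g <- rnorm(1000, 5, 1.5)
  d <- diff_of_means(g + 1, g, seed = 7)
  expect_equal(d$mean, 1, tolerance = 0.02)
})

test_that("swapping groups negates the posterior difference exactly", {
  set.seed(3)
  a <- rnorm(60, 12, 3)
  b <- rnorm(45, 10, 2)
  d1 <- diff_of_means(a, b, seed = 11)
  d2 <- diff_of_means(b, a, seed = 11)
  expect_identical(d1$draws, -d2$draws)
  expect_identical(d1$mean, -d2$mean)
})

test_that("flat-prior intervals approach Welch's t interval for large n", {
  # oracle: classical Welch confidence interval, the large-n flat-prior limit
  set.seed(4)
  a <- rnorm(1000, 14, 4)
  b <- rnorm(1000, 12.5, 2.5)
  d <- diff_of_means(a, b, seed = 13, n_draws = 2e5)
  w <- t.test(a, b)
  expect_lt(abs(d$q2.5 - w$conf.int[1]) / abs(w$conf.int[1]), 0.05)
  expect_lt(abs(d$q97.5 - w$conf.int[2]) / abs(w$conf.int[2]), 0.05)
})

test_that("interval width shrinks like 1/sqrt(n)", {
  widths <- vapply(c(50, 200, 800), function(n) {
    set.seed(n)
    a <- rnorm(n, 10, 2)
    b <- rnorm(n, 10, 2)
    d <- diff_of_means(a, b, seed = 17)
    d$q97.5 - d$q2.5
  }, numeric(1))
  expect_lt(widths[2], widths[1] / 1.6)
  expect_lt(widths[3], widths[2] / 1.6)
})

test_that("robust Student-t likelihood tolerates gross outliers", {
  set.seed(6)
  a <- c(rnorm(150, 11, 1), 300)
  b <- rnorm(150, 10, 1)
  dn <- diff_of_means(a, b, seed = 19)
  dt <- diff_of_means(a, b, seed = 19, likelihood = "student_t",
                      n_draws = 4000)
  expect_lt(abs(dt$mean - 1), 0.5)        # outlier down-weighted
  expect_gt(dn$mean, 2)                   # normal likelihood dragged away
  expect_error(diff_of_means(rep(1, 5), b), "zero variance")
})

test_that("the emitter contrast uses interpolated concentrations by flag", {
  u <- default_universe()
  ar <- attach_exposure(u$areas, krige_to_centroids(u))
  gc <- emitter_contrast(ar, seed = 23)
  expect_equal(gc$n_a + gc$n_b, nrow(ar))
  expect_true(is.finite(gc$mean))
  expect_lte(gc$q2.5, gc$median)
  expect_lte(gc$median, gc$q97.5)
  ar$industry_within_5km <- FALSE
  expect_error(emitter_contrast(ar, seed = 1), "both")
})
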