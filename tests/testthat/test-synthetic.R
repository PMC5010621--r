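test_that("universe invariants hold: bounds, adjacency, ground truth", {
  u <- default_universe()
  bb <- u$bbox
  expect_true(all(u$samples$x_km >= bb[1] & u$samples$x_km <= bb[2]))
  expect_true(all(u$samples$y_km >= bb[3] & u$samples$y_km <= bb[4]))
  expect_true(all(u$areas$x_km >= bb[1] & u$areas$x_km <= bb[2]))
  expect_false(anyDuplicated(u$areas$id) > 0)
  # adjacency irreflexive, stored with i < j (symmetric by construction)
  expect_true(all(u$edges[, 1] < u$edges[, 2]))
  # ICAR identifiability: structured effect sums to zero
  expect_lt(abs(sum(u$truth$u)), 1e-8)
  # concentrations positive with consistent logs
  expect_true(all(u$samples$concentration > 0))
  expect_equal(u$samples$log_concentration, log(u$samples$concentration))
  # three-band sampling density decreases west to east
  xb <- seq(bb[1], bb[2], length.out = 4)
  counts <- table(cut(u$samples$x_km, xb, include.lowest = TRUE))
  expect_true(all(diff(as.numeric(counts)) < 0))
})

test_that("fixed seed reproduces an identical universe", {
  cfg <- sim_config(nx = 6, ny = 6, sample_density = c(0.1, 0.05, 0.01))
  u1 <- simulate_universe(cfg, seed = 5)
  u2 <- simulate_universe(cfg, seed = 5)
  expect_identical(u1$samples, u2$samples)
  expect_identical(u1$areas, u2$areas)
  expect_identical(u1$strata, u2$strata)
  u3 <- simulate_universe(cfg, seed = 6)
  expect_false(identical(u1$samples, u3$samples))
})

test_that("null configuration gives O/E near 1 with unit dispersion", {
  cfg <- sim_config(truth = list(beta = 0, gamma = 0,
                                 delta = c(illiteracy = 0, unemployment = 0),
                                 delta_size = c(semi_urban = 0, urban = 0),
                                 sigma_u = 1e-6, sigma_v = 1e-6),
                    industry = list(shift = 0),
                    sample_density = c(0, 0, 0))
  u <- simulate_universe(cfg, seed = 31)
  O <- u$areas$observed_men
  E <- u$areas$expected_true_men
  expect_equal(sum(O) / sum(E), 1, tolerance = 0.02)
  # dispersion of O around E consistent with Poisson (chi-square at 1% level;
  # deterministic under the fixed seed)
  D <- sum((O - E)^2 / E)
  n <- length(O)
  expect_gt(D, qchisq(0.005, n))
  expect_lt(D, qchisq(0.995, n))
})

test_that("a Poisson GLM on the true exposure recovers the generating log-RR", {
  # oracle: maximum-likelihood Poisson regression against the simulated truth
  cfg <- sim_config(truth = list(beta = log(1.1),
                                 gamma = 0,
                                 delta = c(illiteracy = 0, unemployment = 0),
                                 delta_size = c(semi_urban = 0, urban = 0),
                                 sigma_u = 1e-6, sigma_v = 1e-6,
                                 field = list(sigma = 1)),
                    industry = list(shift = 0),
                    sample_density = c(0, 0, 0))
  u <- simulate_universe(cfg, seed = 47)
  fit <- glm(u$areas$observed_men ~ u$areas$expos_true +
               offset(log(u$areas$expected_true_men)), family = poisson())
  est <- coef(fit)[2]
  se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(est - log(1.1)), 2 * se)
})

test_that("industry placement respects the closed 5 km boundary", {
  areas <- data.frame(id = 1:3, x_km = c(0, 5, 10.01), y_km = 0)
  res <- place_industries(areas, fraction = 0, seed = 1)
  expect_false(any(res$areas$industry_within_5km))
  # emitter exactly 5 km from a centroid: flag is TRUE (closed boundary)
  d <- sqrt((areas$x_km - 5)^2 + (areas$y_km - 5)^2)
  expect_equal(d[2], 5)
  flagged <- d <= 5
  expect_true(flagged[2])
  expect_false(flagged[3])
})

test_that("flagged industry counts match an exhaustive distance check", {
  u <- default_universe()
  res <- place_industries(u$areas[, c("id", "x_km", "y_km")], fraction = 0.1,
                          seed = 99, bbox = u$bbox)
  # oracle: brute-force pairwise distances
  brute <- vapply(seq_len(nrow(u$areas)), function(i) {
    any(sqrt((res$emitters$x_km - u$areas$x_km[i])^2 +
               (res$emitters$y_km - u$areas$y_km[i])^2) <= 5)
  }, logical(1))
  expect_identical(res$areas$industry_within_5km, brute)
  expect_equal(nrow(res$emitters), round(0.1 * nrow(u$areas)))
})

test_that("universe files round-trip through the plain-text formats", {
  cfg <- sim_config(nx = 5, ny = 4, sample_density = c(0.05, 0.02, 0.01))
  u <- simulate_universe(cfg, seed = 8)
  dir <- file.path(tempdir(), "uroundtrip")
  write_universe(u, dir, geojson = TRUE)
  u2 <- read_universe(dir)
  expect_equal(u2$samples$concentration, u$samples$concentration)
  expect_equal(u2$areas$x_km, u$areas$x_km)
  expect_equal(u2$truth$beta, u$truth$beta)
  expect_true(file.exists(file.path(dir, "centroids.geojson")))
  # version guard
  side <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  side$format_version <- 99L
  jsonlite::write_json(side, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(read_universe(dir), "version")
})

test_that("degenerate universes are rejected", {
  cfg <- sim_config(nx = 3, ny = 3, sample_density = c(0, 0, 0),
                    rate_intercept = -Inf)
  expect_error(simulate_universe(cfg, seed = 1), "degenerate|zero")
})
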