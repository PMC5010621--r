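#' Configuration for the synthetic study universe
#'
#' Returns the default desk-scale configuration emulating a national
#' soil-geochemistry / municipal-mortality study: a regular grid of
#' municipalities, three soil-sampling density strata, a latent Matern
#' log-concentration field observed with measurement error, and Poisson death
#' counts under a log-linear relative-risk model with BYM (ICAR + iid) random
#' effects. Any element can be overridden via `...` (nested lists are merged).
#'
#' Default scale is a 20 x 20 grid of 5 km cells (400 areas over 100 x 100 km)
#' with about 1,600 sampling points split over three density bands --- a
#' reduced-scale stand-in for a national universe of ~8,000 towns and ~13,000
#' points with densities of one point per 10, 20 and 100 km2.
#'
#' @param ... overrides, e.g. `truth = list(beta = 0)`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    nx = 20L, ny = 20L, cell_km = 5,
    # sampling points per km2 in three vertical bands (west to east),
    # scaled-down analogue of 1/10, 1/20 and 1/100 km2 national densities
    sample_density = c(0.30, 0.15, 0.03),
    element = "As",
    truth = list(
      alpha = 0,
      beta = log(1.2),            # log-RR per unit log concentration
      effect_type = "continuous_log",  # or "quartile", "ordinal"
      beta_quartile = c(0, log(1.07), log(1.13), log(1.2)),
      log_rr_step = log(1.05),    # per-quartile step for "ordinal"
      delta = c(illiteracy = 0.05, unemployment = 0.05),
      delta_size = c(semi_urban = 0.02, urban = 0.05),
      gamma = 0.10,               # industry-within-5km log-RR
      sigma_u = 0.30, sigma_v = 0.10,
      field = list(range = 30, sigma = 0.7, mean = log(9)),
      sigma_x = 0.45
    ),
    industry = list(fraction = 0.10, radius = 5, shift = 0.10,
                    shift_range = 10),
    population = list(meanlog = log(1800), sdlog = 1.0, growth = 0.04),
    rate_intercept = -12.0, rate_slope = 0.5,
    rate_sex = c(men = 1.4, women = 0.8), rate_period2 = 0.95
  )
  over <- list(...)
  merge_lists(cfg, over)
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

age_groups <- function() {
  c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
}

# Fixed age pyramid (fractions of total population in 18 five-year groups);
# flat through mid-life with attrition at older ages, loosely matching a
# southern-European municipal age structure.
age_pyramid <- function() {
  w <- c(rep(1, 12), 0.9, 0.8, 0.65, 0.5, 0.35, 0.2)
  w / sum(w)
}

# Reference death rates per person-year by stratum (generating truth).
baseline_rates <- function(config) {
  ag <- age_groups()
  g <- expand.grid(age_group = ag, sex = c("men", "women"),
                   period = c("1999-2003", "2004-2008"),
                   stringsAsFactors = FALSE)
  gi <- match(g$age_group, ag)
  g$rate <- exp(config$rate_intercept + config$rate_slope * (gi - 1)) *
    config$rate_sex[g$sex] *
    ifelse(g$period == "2004-2008", config$rate_period2, 1)
  rownames(g) <- NULL
  g
}

#' Mark areas lying within a fixed radius of simulated industrial emitters
#'
#' Emitter coordinates are drawn uniformly over the bounding box (one emitter
#' per `round(fraction * n_areas)`), and each area is flagged when its centroid
#' lies within `radius` km of any emitter. The 5 km radius is treated as a
#' closed boundary: a centroid at exactly `radius` km is flagged.
#'
#' @param areas data frame with columns `x_km`, `y_km`.
#' @param fraction emitters per area, in `[0, 1]`.
#' @param seed integer seed.
#' @param radius flag radius in km (default 5).
#' @param bbox numeric `c(xmin, xmax, ymin, ymax)`; defaults to the range of
#'   the centroids.
#' @return list with `areas` (input plus logical `industry_within_5km`) and
#'   `emitters` (data frame of emitter coordinates, possibly empty).
#' @export
place_industries <- function(areas, fraction, seed, radius = 5, bbox = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nrow(areas)
  n_emit <- round(fraction * n)
  if (is.null(bbox)) {
    bbox <- c(range(areas$x_km), range(areas$y_km))
  }
  if (n_emit == 0) {
    areas$industry_within_5km <- rep(FALSE, n)
    return(list(areas = areas,
                emitters = data.frame(x_km = numeric(0), y_km = numeric(0))))
  }
  em <- with_seed(seed, data.frame(
    x_km = runif(n_emit, bbox[1], bbox[2]),
    y_km = runif(n_emit, bbox[3], bbox[4])))
  d <- pdist(cbind(areas$x_km, areas$y_km), cbind(em$x_km, em$y_km))
  areas$industry_within_5km <- apply(d, 1, min) <= radius
  list(areas = areas, emitters = em)
}

#' Simulate a complete synthetic study universe with known ground truth
#'
#' Composes the generative model end-to-end: a Matern log-concentration field
#' over the domain, lognormal point observations of soil concentration with
#' measurement error, municipal centroids on a regular grid with ICAR + iid
#' area effects, socio-demographic covariates, industrial emitters, stratified
#' populations (18 age groups x 2 sexes x 2 quinquennia) and Poisson death
#' counts under the log-linear relative-risk model. Deterministic given
#' `(config, seed)`.
#'
#' @param config a [sim_config()] list.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return object of class `study_universe`: list with `bbox`, `areas`,
#'   `samples`, `strata` (long-format population/death table), `edges`
#'   (adjacency), `rates` (generating reference rates), `emitters`, `truth`
#'   (ground-truth parameters and latent vectors), `config`, `seed`.
#' @export
simulate_universe <- function(config = sim_config(), seed = 1L) {
  tr <- config$truth
  stopifnot(tr$sigma_u > 0, tr$sigma_v > 0, tr$sigma_x > 0)
  nx <- config$nx; ny <- config$ny; h <- config$cell_km
  n <- nx * ny
  bbox <- c(0, nx * h, 0, ny * h)

  # municipal centroids at cell centres, row-major (x fastest)
  gx <- (seq_len(nx) - 0.5) * h
  gy <- (seq_len(ny) - 0.5) * h
  cent <- cbind(x_km = rep(gx, ny), y_km = rep(gy, each = nx))
  edges <- grid_adjacency(nx, ny)

  # sampling points in three vertical density bands
  dens <- config$sample_density
  xb <- seq(bbox[1], bbox[2], length.out = length(dens) + 1)
  band_area <- diff(xb) * (bbox[4] - bbox[3])
  n_band <- round(dens * band_area)
  samp <- with_seed(derive_seed(seed, "samples"), {
    do.call(rbind, lapply(seq_along(dens), function(b) {
      cbind(x_km = runif(n_band[b], xb[b], xb[b + 1]),
            y_km = runif(n_band[b], bbox[3], bbox[4]))
    }))
  })
  if (is.null(samp)) samp <- matrix(numeric(0), 0, 2,
                                    dimnames = list(NULL, c("x_km", "y_km")))
  ns <- nrow(samp)

  # latent field jointly at samples and centroids
  fp <- matern_params(tr$field$range, tr$field$sigma, tr$field$mean)
  x_all <- simulate_matern_field(rbind(samp, cent), fp,
                                 derive_seed(seed, "field"))

  # industrial emitters; optional local upward shift of the field mean
  areas <- data.frame(id = seq_len(n), x_km = cent[, 1], y_km = cent[, 2])
  pi_res <- place_industries(areas, config$industry$fraction,
                             derive_seed(seed, "industry"),
                             radius = config$industry$radius, bbox = bbox)
  areas <- pi_res$areas
  emitters <- pi_res$emitters
  if (nrow(emitters) > 0 && config$industry$shift != 0) {
    dd <- pdist(rbind(samp, cent), cbind(emitters$x_km, emitters$y_km))
    bump <- config$industry$shift *
      rowSums(exp(-dd^2 / (2 * config$industry$shift_range^2)))
    x_all <- x_all + bump
  }

  # observed concentrations (lognormal around the field)
  log_c <- x_all[seq_len(ns)] +
    with_seed(derive_seed(seed, "meas"), rnorm(ns, 0, tr$sigma_x))
  samples <- data.frame(sample_id = seq_len(ns), x_km = samp[, 1],
                        y_km = samp[, 2], concentration = exp(log_c),
                        log_concentration = log_c)
  expos_true <- x_all[ns + seq_len(n)]

  # area random effects
  ic <- simulate_icar(edges, n, tr$sigma_u, derive_seed(seed, "icar"))
  u <- ic$u
  v <- with_seed(derive_seed(seed, "iid"), rnorm(n, 0, tr$sigma_v))

  # socio-demographic covariates and population sizes
  soc <- with_seed(derive_seed(seed, "soc"), {
    data.frame(illiteracy = rnorm(n), unemployment = rnorm(n))
  })
  pop_total <- with_seed(derive_seed(seed, "pop"), {
    exp(rnorm(n, config$population$meanlog, config$population$sdlog))
  })
  size_class <- cut(pop_total, c(-Inf, 2000, 10000, Inf),
                    labels = c("rural", "semi_urban", "urban"))
  areas$illiteracy <- soc$illiteracy
  areas$unemployment <- soc$unemployment
  areas$size_class <- as.character(size_class)
  areas$population <- pop_total

  # exposure effect term
  q_true <- NULL
  eff <- switch(tr$effect_type,
    continuous_log = tr$beta * (expos_true - tr$field$mean),
    quartile = {
      q_true <- quartile_code(expos_true)$quartile
      tr$beta_quartile[q_true]
    },
    ordinal = {
      q_true <- quartile_code(expos_true)$quartile
      tr$log_rr_step * (q_true - 1)
    },
    stop("unknown effect_type: ", tr$effect_type))

  log_lambda <- tr$alpha + eff +
    tr$delta["illiteracy"] * areas$illiteracy +
    tr$delta["unemployment"] * areas$unemployment +
    ifelse(areas$size_class == "semi_urban", tr$delta_size["semi_urban"],
           ifelse(areas$size_class == "urban", tr$delta_size["urban"], 0)) +
    tr$gamma * areas$industry_within_5km + u + v
  lambda <- exp(unname(log_lambda))

  # stratified populations, person-years and Poisson deaths
  rates <- baseline_rates(config)
  pyr <- age_pyramid()
  ag <- age_groups()
  strata <- expand.grid(area_id = seq_len(n), age_group = ag,
                        sex = c("men", "women"),
                        period = c("1999-2003", "2004-2008"),
                        stringsAsFactors = FALSE)
  gi <- match(strata$age_group, ag)
  base_pop <- pop_total[strata$area_id] * pyr[gi] / 2   # split over 2 sexes
  strata$population <- base_pop *
    ifelse(strata$period == "2004-2008", 1 + config$population$growth, 1)
  key <- paste(strata$age_group, strata$sex, strata$period)
  rkey <- paste(rates$age_group, rates$sex, rates$period)
  strata$rate <- rates$rate[match(key, rkey)]
  mu <- strata$population * 5 * strata$rate * lambda[strata$area_id]
  if (sum(mu) <= 0) stop("degenerate universe: all Poisson means are zero")
  strata$deaths <- with_seed(derive_seed(seed, "deaths"),
                             rpois(nrow(strata), mu))
  strata$rate <- NULL

  # per-area observed and (generating-rate) expected deaths by sex
  for (sx in c("men", "women")) {
    sel <- strata$sex == sx
    areas[[paste0("observed_", sx)]] <-
      as.vector(tapply(strata$deaths[sel], strata$area_id[sel], sum))
    areas[[paste0("expected_true_", sx)]] <-
      as.vector(tapply(strata$population[sel] * 5 *
                         rates$rate[match(key, rkey)][sel],
                       strata$area_id[sel], sum))
  }
  areas$expos_true <- expos_true

  truth <- tr
  truth$u <- u
  truth$v <- v
  truth$lambda <- lambda
  truth$expos_true <- expos_true
  truth$quartile_true <- q_true

  structure(list(bbox = bbox, areas = areas, samples = samples,
                 strata = strata, edges = edges, rates = rates,
                 emitters = emitters, truth = truth, config = config,
                 seed = seed),
            class = "study_universe")
}

#' @export
print.study_universe <- function(x, ...) {
  cat("Synthetic study universe:", nrow(x$areas), "areas,",
      nrow(x$samples), "soil samples\n")
  cat("  domain:", x$bbox[2] - x$bbox[1], "x", x$bbox[4] - x$bbox[3], "km;",
      "element:", x$config$element, "\n")
  cat("  observed deaths (men/women):",
      sum(x$areas$observed_men), "/", sum(x$areas$observed_women), "\n")
  invisible(x)
}

#' Write a study universe to plain-text files
#'
#' Emits `samples.csv`, `areas.csv`, `strata.csv`, `adjacency.csv` (edge
#' list), `truth.json` (ground truth, seed and config echo) and optionally
#' `centroids.geojson`.
#'
#' @param universe a `study_universe`.
#' @param dir output directory (created if needed).
#' @param geojson also write a GeoJSON point file of centroids.
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir, geojson = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(universe$samples, file.path(dir, "samples.csv"))
  write_table_csv(universe$areas, file.path(dir, "areas.csv"))
  write_table_csv(universe$strata, file.path(dir, "strata.csv"))
  write_table_csv(as.data.frame(universe$edges),
                  file.path(dir, "adjacency.csv"))
  sidecar <- list(format_version = 1L, seed = universe$seed,
                  bbox = universe$bbox, config = universe$config,
                  truth = universe$truth[setdiff(names(universe$truth),
                                                 c("lambda"))])
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (geojson) {
    feats <- lapply(seq_len(nrow(universe$areas)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(universe$areas$x_km[i],
                                           universe$areas$y_km[i])),
           properties = list(id = universe$areas$id[i]))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         file.path(dir, "centroids.geojson"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a study universe written by [write_universe()]
#' @param dir directory containing the universe files.
#' @return a `study_universe` (ground-truth latent vectors restored from the
#'   JSON sidecar).
#' @export
read_universe <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  if (is.null(side$format_version) || side$format_version != 1L) {
    stop("unknown universe format version in ", file.path(dir, "truth.json"))
  }
  structure(list(bbox = side$bbox,
                 areas = read_table_csv(file.path(dir, "areas.csv")),
                 samples = read_table_csv(file.path(dir, "samples.csv")),
                 strata = read_table_csv(file.path(dir, "strata.csv")),
                 edges = as.matrix(read_table_csv(file.path(dir, "adjacency.csv"))),
                 rates = NULL, emitters = NULL,
                 truth = side$truth, config = side$config, seed = side$seed),
            class = "study_universe")
}
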