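#' Ordinary kriging of point samples onto target locations
#'
#' Solves, per target, the ordinary-kriging system in covariance form with a
#' Lagrange multiplier enforcing unit weight sum:
#' \deqn{\begin{pmatrix} K & 1 \\ 1^T & 0 \end{pmatrix}
#'       \begin{pmatrix} w \\ m \end{pmatrix} =
#'       \begin{pmatrix} k_0 \\ 1 \end{pmatrix}}
#' where `K[a,b] = psill * rho(d_ab) + nugget * 1(a = b)` and
#' `k0[a] = psill * rho(d_a0)` (the nugget is not carried to the target, so
#' the kriging variance is 0 at a sampled location only when the nugget is 0).
#' The kriging variance is `nugget + psill - w' k0 - m`.
#'
#' For scalability the system is solved over the `n_neighbours` nearest
#' samples of each target (spec default 64); `n_neighbours = Inf` gives the
#' global dense solve used as the oracle path. Nearest-neighbour ties at equal
#' distance are broken by sample order (deterministic).
#'
#' @param samples data frame with `x_km`, `y_km` and the value column.
#' @param model a [variogram_model()].
#' @param targets matrix or data frame of target coordinates (`x_km`, `y_km`).
#' @param n_neighbours neighbourhood size (default 64).
#' @param value name of the value column (default `"log_concentration"`).
#' @return data frame `x_km`, `y_km`, `pred`, `krig_var`, plus attribute
#'   `"min_weight"` (most negative kriging weight seen, for diagnostics).
#' @export
ordinary_kriging <- function(samples, model, targets, n_neighbours = 64,
                             value = "log_concentration") {
  stopifnot(nrow(samples) >= 2, inherits(model, "variogram_model"))
  xy <- as.matrix(cbind(samples$x_km, samples$y_km))
  z <- samples[[value]]
  tg <- if (is.data.frame(targets) && all(c("x_km", "y_km") %in% names(targets))) {
    as.matrix(targets[, c("x_km", "y_km")])
  } else {
    as.matrix(targets)[, 1:2, drop = FALSE]
  }
  n <- nrow(xy)
  k <- min(n_neighbours, n)

  dup <- pdist(xy)
  diag(dup) <- Inf
  if (model$nugget == 0 && any(dup < 1e-12)) {
    pr <- which(dup < 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "duplicate sample locations %d and %d make the kriging system singular (zero nugget)",
      min(pr), max(pr)))
  }

  sill <- model$nugget + model$psill
  cov_fun <- function(d) model$psill *
    variogram_correlation(d, model$family, model$range)

  dt <- pdist(tg, xy)
  preds <- numeric(nrow(tg))
  kvar <- numeric(nrow(tg))
  min_w <- Inf
  for (t in seq_len(nrow(tg))) {
    ord <- order(dt[t, ], seq_len(n))  # ties broken by sample order
    nb <- sort(ord[seq_len(k)])
    K <- cov_fun(dup[nb, nb, drop = FALSE])
    K[!is.finite(K)] <- 0              # diag of dup is Inf
    diag(K) <- sill
    k0 <- cov_fun(dt[t, nb])
    A <- rbind(cbind(K, 1), c(rep(1, length(nb)), 0))
    rhs <- c(k0, 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) {
      stop("singular kriging system at target ", t, ": ",
           conditionMessage(e))
    })
    w <- sol[seq_along(nb)]
    m <- sol[length(sol)]
    preds[t] <- sum(w * z[nb])
    kvar[t] <- max(0, sill - sum(w * k0) - m)
    min_w <- min(min_w, w)
  }
  out <- data.frame(x_km = tg[, 1], y_km = tg[, 2], pred = preds,
                    krig_var = kvar)
  attr(out, "min_weight") <- min_w
  out
}

#' Krige sample log concentrations onto municipal centroids
#'
#' Convenience wrapper: fits (or takes) a variogram model on log
#' concentrations and kriges onto the area centroids, returning one prediction
#' per area id.
#'
#' @param universe a `study_universe` (or list with `samples` and `areas`).
#' @param model optional `variogram_model`; fitted from the samples when NULL.
#' @param n_neighbours kriging neighbourhood size.
#' @param family variogram family used when fitting.
#' @return data frame `area_id`, `x_km`, `y_km`, `pred_log`, `krig_var`.
#' @export
krige_to_centroids <- function(universe, model = NULL, n_neighbours = 64,
                               family = "matern_nu1") {
  if (is.null(model)) {
    ev <- empirical_variogram(universe$samples)
    model <- fit_variogram(ev, family = family)
  }
  pr <- ordinary_kriging(universe$samples, model,
                         universe$areas[, c("x_km", "y_km")],
                         n_neighbours = n_neighbours)
  data.frame(area_id = universe$areas$id, x_km = pr$x_km, y_km = pr$y_km,
             pred_log = pr$pred, krig_var = pr$krig_var)
}

#' Attach kriged exposure to the areas table
#'
#' Joins predictions to areas by id; every area must receive exactly one
#' prediction. The kriged log concentration becomes the `expos` column and the
#' kriging variance is kept alongside for diagnostics.
#'
#' @param areas areas data frame with an `id` column.
#' @param predictions data frame with `area_id`, `pred_log`, `krig_var`.
#' @return areas with `expos` and `krig_var` columns.
#' @export
attach_exposure <- function(areas, predictions) {
  if (anyDuplicated(predictions$area_id)) {
    stop("duplicate area_id in predictions")
  }
  unknown <- setdiff(predictions$area_id, areas$id)
  if (length(unknown) > 0) {
    stop("predictions refer to unknown area ids: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  idx <- match(areas$id, predictions$area_id)
  if (anyNA(idx)) {
    stop("missing predictions for area ids: ",
         paste(head(areas$id[is.na(idx)], 5), collapse = ", "))
  }
  areas$expos <- predictions$pred_log[idx]
  areas$krig_var <- predictions$krig_var[idx]
  areas
}
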