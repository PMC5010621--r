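#' Theoretical semivariogram and correlation families
#'
#' Supported families: `matern_nu1` (Matern with smoothness 1, `range` = the
#' practical range, as in [matern_correlation()]), `exponential`
#' (`rho = exp(-h / range)`, practical range `3 * range`) and `spherical`
#' (`range` = the exact range beyond which correlation is 0).
#'
#' @param h lags (km).
#' @param family one of `"matern_nu1"`, `"exponential"`, `"spherical"`.
#' @param range family range parameter (> 0).
#' @return correlations at lags `h`.
#' @export
variogram_correlation <- function(h, family, range) {
  stopifnot(range > 0)
  switch(family,
    matern_nu1 = matern_correlation(h, range),
    exponential = exp(-h / range),
    spherical = ifelse(h >= range, 0,
                       1 - 1.5 * h / range + 0.5 * (h / range)^3),
    stop("unknown variogram family: ", family))
}

#' Construct a variogram model
#'
#' Semivariance `gamma(h) = nugget + psill * (1 - rho(h))` for `h > 0`,
#' `gamma(0) = 0`.
#'
#' @param family correlation family (see [variogram_correlation()]).
#' @param nugget nugget variance (>= 0).
#' @param psill partial sill (> 0).
#' @param range range parameter (> 0).
#' @param flagged logical; set when a fit hit optimiser bounds.
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(family = "matern_nu1", nugget = 0, psill = 1,
                            range = 1, flagged = FALSE) {
  stopifnot(nugget >= 0, psill > 0, range > 0)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range, flagged = flagged),
            class = "variogram_model")
}

#' Evaluate a variogram model's semivariance
#' @param model a `variogram_model`.
#' @param h lags (km).
#' @return semivariances; 0 at `h = 0`.
#' @export
semivariance <- function(model, h) {
  g <- model$nugget +
    model$psill * (1 - variogram_correlation(h, model$family, model$range))
  g[h == 0] <- 0
  g
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("Variogram model [%s]: nugget %.4g, partial sill %.4g, range %.4g%s\n",
              x$family, x$nugget, x$psill, x$range,
              if (isTRUE(x$flagged)) " (flagged: fit at bounds)" else ""))
  invisible(x)
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all sample pairs by separation distance and computes the classical
#' estimator `gamma(h) = (1 / 2N_h) * sum (z_a - z_b)^2` per bin. Bins with no
#' pairs are dropped (and reported via the `dropped_bins` attribute).
#'
#' @param samples data frame with `x_km`, `y_km` and a value column.
#' @param n_bins number of equal-width lag bins (>= 1).
#' @param max_lag maximum lag considered (km).
#' @param value name of the value column (default `"log_concentration"`).
#' @return data frame `lag` (bin midpoint), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(samples, n_bins = 15, max_lag = NULL,
                                value = "log_concentration") {
  stopifnot(nrow(samples) >= 2, n_bins >= 1)
  xy <- cbind(samples$x_km, samples$y_km)
  z <- samples[[value]]
  d <- pdist(xy)
  iu <- upper.tri(d)
  dv <- d[iu]
  if (is.null(max_lag)) max_lag <- max(dv) / 2
  keep <- dv > 0 & dv <= max_lag
  if (!any(keep)) stop("no sample pairs within max_lag = ", max_lag, " km")
  sq <- (outer(z, z, "-")^2)[iu][keep]
  dv <- dv[keep]
  br <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(dv, br, rightmost.closed = TRUE), 1L), n_bins)
  np <- tabulate(bin, n_bins)
  g <- rep(NA_real_, n_bins)
  gs <- tapply(sq, factor(bin, levels = seq_len(n_bins)), sum)
  g[np > 0] <- gs[np > 0] / (2 * np[np > 0])
  out <- data.frame(lag = (br[-1] + br[-length(br)]) / 2,
                    gamma = g, n_pairs = np)
  dropped <- which(np == 0)
  out <- out[np > 0, , drop = FALSE]
  attr(out, "dropped_bins") <- dropped
  rownames(out) <- NULL
  out
}

#' Fit a variogram model to an empirical variogram by weighted least squares
#'
#' Minimises `sum N_h * (gamma_hat(h) - gamma_model(h))^2` over nugget,
#' partial sill and range with bounded optimisation (`nlminb`) from a fixed
#' grid of starting values, so the fit is deterministic. A fit whose range or
#' sill lands on the optimisation bounds is flagged.
#'
#' @param empirical output of [empirical_variogram()] (>= 3 bins).
#' @param family variogram family.
#' @return a `variogram_model`.
#' @export
fit_variogram <- function(empirical, family = "matern_nu1") {
  stopifnot(nrow(empirical) >= 3)
  h <- empirical$lag
  g <- empirical$gamma
  w <- empirical$n_pairs
  s0 <- max(g)
  hmax <- max(h)
  lower <- c(0, 1e-8 * s0, hmax * 1e-3)
  upper <- c(2 * s0, 4 * s0, hmax * 10)
  obj <- function(p) sum(w * (g - (p[1] + p[2] *
    (1 - variogram_correlation(h, family, p[3]))))^2)
  starts <- expand.grid(n = c(0, 0.25 * s0), s = c(0.5, 1) * s0,
                        r = c(0.25, 0.5, 1.5) * hmax)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      nlminb(as.numeric(starts[k, ]), obj, lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("variogram fit failed from every start")
  p <- best$par
  at_bound <- p[3] <= lower[3] * (1 + 1e-6) || p[3] >= upper[3] * (1 - 1e-6) ||
    p[2] >= upper[2] * (1 - 1e-6) || p[2] <= lower[2] * (1 + 1e-6)
  if (at_bound) {
    warning("variogram fit hit optimisation bounds; model flagged")
  }
  variogram_model(family = family, nugget = p[1],
                  psill = max(p[2], 1e-8 * s0), range = p[3],
                  flagged = at_bound)
}
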