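#' Matern correlation function with smoothness nu = 1
#'
#' Correlation \eqn{r(d) = \kappa d \, K_1(\kappa d)} with \eqn{r(0) = 1},
#' where \eqn{K_1} is the modified Bessel function of the second kind. The
#' scale is parameterised by the practical range \eqn{\rho = \sqrt{8\nu}/\kappa
#' = \sqrt{8}/\kappa}, the distance at which correlation drops to about 0.13.
#' Smoothness nu = 1 corresponds to the standard two-dimensional SPDE operator
#' with alpha = 2.
#'
#' @param d distances (same units as `range`), vector or matrix.
#' @param range practical range \eqn{\rho > 0}.
#' @return correlations in (0, 1], same shape as `d`.
#' @export
matern_correlation <- function(d, range) {
  stopifnot(range > 0)
  kappa <- sqrt(8) / range
  x <- kappa * d
  out <- x * besselK(x, 1)
  out[d == 0] <- 1
  # besselK underflows to 0 for very large x, which is the correct limit
  out[is.na(out) & d > 0] <- 0
  out
}

#' Parameters of a stationary Matern (nu = 1) Gaussian field
#'
#' @param range practical range in km (> 0).
#' @param sigma marginal standard deviation (> 0).
#' @param mean constant field mean on the log-concentration scale.
#' @return object of class `matern_params`.
#' @export
matern_params <- function(range, sigma, mean = 0) {
  stopifnot(range > 0, sigma > 0, is.finite(mean))
  structure(list(range = range, sigma = sigma, mean = mean),
            class = "matern_params")
}

#' Simulate one exact draw of a Matern (nu = 1) Gaussian field
#'
#' Draws the field jointly at the given locations by dense Cholesky
#' factorisation of the Matern covariance matrix. Intended for simulation of
#' ground truth at up to a few thousand locations; the sparse SPDE
#' representation ([assemble_spde()]) is the scalable route.
#'
#' @param locations numeric matrix (n x 2) of planar km coordinates.
#' @param params a [matern_params()] object.
#' @param seed integer seed; the draw is a deterministic function of
#'   `(locations, params, seed)`.
#' @param jitter small nugget added to the covariance diagonal for numerical
#'   positive-definiteness.
#' @return numeric vector of field values (mean `params$mean`).
#' @export
simulate_matern_field <- function(locations, params, seed, jitter = 1e-10) {
  locations <- as.matrix(locations)
  stopifnot(nrow(locations) >= 1, ncol(locations) == 2,
            inherits(params, "matern_params"))
  d <- pdist(locations)
  if (jitter <= 0) {
    dup <- which(d < 1e-12 & upper.tri(d), arr.ind = TRUE)
    if (nrow(dup) > 0) {
      stop(sprintf(
        "duplicate locations make the covariance singular (first pair: %d, %d)",
        dup[1, 1], dup[1, 2]))
    }
  }
  S <- params$sigma^2 * matern_correlation(d, params$range)
  diag(S) <- diag(S) + max(jitter, 0)
  L <- tryCatch(chol(S), error = function(e) {
    dup <- which(d < 1e-9 & upper.tri(d), arr.ind = TRUE)
    if (nrow(dup) > 0) {
      stop(sprintf(
        "covariance not positive definite; near-duplicate locations (first pair: %d, %d)",
        dup[1, 1], dup[1, 2]))
    }
    stop("covariance not positive definite: ", conditionMessage(e))
  })
  z <- with_seed(seed, rnorm(nrow(locations)))
  params$mean + drop(crossprod(L, z))
}
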