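#' Quartile coding of an exposure vector
#'
#' Cut points are the 25/50/75 empirical percentiles under the
#' linear-interpolation rule (R's default type-7 quantiles). Intervals are
#' half-open `[low, high)` except the last, which is closed; the first
#' quartile is the reference category in model fits.
#'
#' @param exposures numeric vector with at least 4 distinct values.
#' @return list with `quartile` (integer 1-4 per element), `cuts` (3 cut
#'   points), `levels` (`"q1".."q4"`) and `counts`.
#' @export
quartile_code <- function(exposures) {
  if (length(unique(exposures)) < 4) {
    stop("need at least 4 distinct exposure values for quartile coding")
  }
  cuts <- unname(quantile(exposures, c(0.25, 0.5, 0.75), type = 7))
  if (any(diff(cuts) <= 0)) {
    stop("tied exposure values collapse a quartile to empty; ",
         "use continuous coding instead")
  }
  q <- 1L + (exposures >= cuts[1]) + (exposures >= cuts[2]) +
    (exposures >= cuts[3])
  counts <- tabulate(q, 4L)
  if (any(counts == 0)) {
    stop("a quartile is empty; use continuous coding instead")
  }
  list(quartile = as.integer(q), cuts = cuts,
       levels = paste0("q", 1:4), counts = counts)
}

#' Specification of the ecological BYM regression
#'
#' @param coding exposure coding: `"quartile_factor"` (q1 reference),
#'   `"quartile_ordinal"` (quartile 1-4 entered as a continuous trend) or
#'   `"continuous_log"` (the log concentration itself).
#' @param exposure name of the exposure column in the areas table.
#' @param covariates names of continuous socio-demographic covariate columns
#'   (standardised or not); empty for the unadjusted model.
#' @param size_class name of the population-size class column
#'   (rural/semi_urban/urban factor, rural reference), or NULL.
#' @param industry name of the logical industry-proximity column, or NULL.
#' @param random_effects include the BYM (ICAR + iid) area effects; disable
#'   to clamp them at zero (plain Poisson regression, the GLM limit).
#' @param priors a [prior_config()].
#' @return a `bym_spec` list.
#' @export
bym_spec <- function(coding = c("quartile_factor", "quartile_ordinal",
                                "continuous_log"),
                     exposure = "expos", covariates = character(0),
                     size_class = NULL, industry = NULL,
                     random_effects = TRUE, priors = prior_config()) {
  coding <- match.arg(coding)
  structure(list(coding = coding, exposure = exposure,
                 covariates = covariates, size_class = size_class,
                 industry = industry, random_effects = random_effects,
                 priors = priors),
            class = "bym_spec")
}

# Design matrix (including intercept) for a bym_spec; returns list(X, terms,
# quartiles) where terms names the columns after the intercept.
build_design <- function(areas, spec) {
  n <- nrow(areas)
  expos <- areas[[spec$exposure]]
  if (is.null(expos)) stop("exposure column not found: ", spec$exposure)
  qc <- NULL
  if (spec$coding == "quartile_factor") {
    qc <- quartile_code(expos)
    Xe <- sapply(2:4, function(k) as.numeric(qc$quartile == k))
    colnames(Xe) <- paste0("rr_q", 2:4)
  } else if (spec$coding == "quartile_ordinal") {
    qc <- quartile_code(expos)
    Xe <- matrix(as.numeric(qc$quartile), ncol = 1,
                 dimnames = list(NULL, "rr_trend"))
  } else {
    Xe <- matrix(expos, ncol = 1, dimnames = list(NULL, "rr_log"))
  }
  X <- cbind(intercept = rep(1, n), Xe)
  for (cv in spec$covariates) {
    if (is.null(areas[[cv]])) stop("covariate column not found: ", cv)
    X <- cbind(X, areas[[cv]])
    colnames(X)[ncol(X)] <- cv
  }
  if (!is.null(spec$size_class)) {
    sc <- areas[[spec$size_class]]
    X <- cbind(X, semi_urban = as.numeric(sc == "semi_urban"),
               urban = as.numeric(sc == "urban"))
  }
  if (!is.null(spec$industry)) {
    X <- cbind(X, industry = as.numeric(areas[[spec$industry]]))
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  list(X = X, qc = qc)
}

#' Fit the Bayesian Poisson BYM ecological regression
#'
#' Model: `O_i ~ Poisson(E_i * lambda_i)` with
#' `log(lambda_i) = x_i' theta + u_i + v_i`, where `u` follows an intrinsic
#' CAR prior on the area adjacency with a sum-to-zero constraint per connected
#' component (SD `sigma_u`), `v` is iid Normal(0, `sigma_v`^2), and the fixed
#' effects `theta` (intercept, exposure coding, confounders) have Normal(0,
#' `fixed_sd`^2) priors. Posterior sampling is by Metropolis-Hastings: the
#' full latent block `(theta, u, v)` is updated jointly from a sparse
#' Gaussian approximation (Taylor expansion of the Poisson likelihood) with
#' the constraint enforced by conditioning, and the half-Normal-prior SDs by
#' adaptive random-walk MH on the log scale (adaptation during burn-in only).
#' Isolated areas (no neighbours) carry only the iid effect.
#'
#' @param areas areas data frame.
#' @param edges adjacency edge list (two-column matrix).
#' @param observed,expected names of the observed/expected death columns
#'   (e.g. `"observed_men"`, `"expected_men"`).
#' @param spec a [bym_spec()].
#' @param mcmc an [mcmc_config()].
#' @return object of class `bym_fit`: posterior `summary` table (mean,
#'   quantiles, RR scale where applicable), `lambda` per-area smoothed
#'   relative-risk summaries, `draws` (fixed effects and SDs), `diagnostics`
#'   (split R-hat, effective sample size, acceptance rates) and `flagged`
#'   (TRUE when any reported R-hat exceeds 1.05).
#' @export
fit_bym <- function(areas, edges, observed, expected, spec = bym_spec(),
                    mcmc = mcmc_config()) {
  O <- areas[[observed]]
  E <- areas[[expected]]
  if (is.null(O) || is.null(E)) stop("observed/expected columns not found")
  stopifnot(all(O >= 0), all(E >= 0), abs(O - round(O)) < 1e-8)
  if (sum(E) <= 0) stop("all expected counts are zero")
  n <- length(O)
  des <- build_design(areas, spec)
  X <- des$X
  p <- ncol(X)
  offset <- log(pmax(E, 1e-12))
  pri <- spec$priors

  re <- isTRUE(spec$random_effects)
  if (re) {
    edges <- check_edges(edges, n)
    R <- icar_structure(edges, n)
    comp <- graph_components(edges, n)
    deg <- Matrix::diag(R)
    conn <- tabulate(comp)[comp] > 1          # areas in components of size > 1
    ncomp_conn <- length(unique(comp[conn]))
    # constraint matrix: per connected component (size > 1), sum of u = 0
    Acon <- Matrix::sparseMatrix(
      i = match(comp[conn], sort(unique(comp[conn]))),
      j = p + which(conn), x = 1, dims = c(ncomp_conn, p + 2 * n))
    Mmat <- to_dgc(cbind(Matrix::Matrix(X, sparse = TRUE),
                         Matrix::Diagonal(n), Matrix::Diagonal(n)))
    dim_z <- p + 2 * n
    tmpl <- bym_prior_template(p, n, R, !conn, pri$fixed_sd)
    qt <- quad_template(Mmat, priors = list(bym_prior_precision(tmpl, 1, 1)))
  } else {
    Mmat <- to_dgc(Matrix::Matrix(X, sparse = TRUE))
    dim_z <- p
    Acon <- NULL
    Pfix <- Matrix::forceSymmetric(to_dgc(
      Matrix::Diagonal(p, 1 / pri$fixed_sd^2)))
    qt <- quad_template(Mmat, priors = list(Pfix))
  }

  # initial values from a Poisson GLM
  init <- tryCatch(
    coef(glm(O ~ X - 1 + offset(offset), family = poisson())),
    error = function(e) rep(0, p))
  init[!is.finite(init)] <- 0

  set.seed(mcmc$seed)
  z <- c(init, rep(0, dim_z - p))
  mode_env <- new.env()
  mode_env$z_hat <- z
  sigma_u <- 0.2; sigma_v <- 0.1
  {
    P0 <- if (re) bym_prior_precision(tmpl, sigma_u, sigma_v) else Pfix
    P0x <- P0@x
    z <- laplace_init(z, P0, rep(0, dim_z), Mmat, offset, O, Acon, mode_env,
                      function(b) quad_build(qt, list(P0x), b))
  }
  scale_u <- 0.4; scale_v <- 0.4
  scale_u2 <- 0.2; scale_v2 <- 0.2
  scale_hl <- 0.3
  if (re) rank_R <- sum(conn) - ncomp_conn
  total <- mcmc$burnin + mcmc$n_iter
  keep_cf <- matrix(NA_real_, mcmc$n_iter, p,
                    dimnames = list(NULL, colnames(X)))
  keep_sig <- matrix(NA_real_, mcmc$n_iter, 2,
                     dimnames = list(NULL, c("sigma_u", "sigma_v")))
  lam_sum <- numeric(n); lam_ssq <- numeric(n)
  lam_draws <- matrix(NA_real_, ceiling(mcmc$n_iter / mcmc$thin), n)
  acc_lat <- 0
  kd <- 0

  for (it in seq_len(total)) {
    # prior precision of (theta, u, v) given current SDs; isolated areas'
    # u is pinned near zero by a stiff diagonal entry in the template
    P <- if (re) bym_prior_precision(tmpl, sigma_u, sigma_v) else Pfix
    Px <- P@x
    st <- gmrf_mh_step(z, P, rep(0, dim_z), Mmat, offset, O, Acon,
                       mode_env = mode_env,
                       Qc_build = function(b) quad_build(qt, list(Px), b),
                       adapt = it <= mcmc$burnin,
                       local_stage = it %% 2 == 0 || it <= 20)
    z <- st$z
    if (it > mcmc$burnin) acc_lat <- acc_lat + st$accepted

    # joint (sigma_u, sigma_v, latent) one-block move
    if (re) {
      hl <- hyper_latent_step(z, log(sigma_u), log(sigma_v),
        P_build = function(su, sv) bym_prior_precision(tmpl, su, sv),
        blin = rep(0, dim_z), M = Mmat, offset = offset, O = O, A = Acon,
        rank_R = rank_R, n = n, pri = pri, scale = scale_hl,
        mode_env = mode_env,
        Qc_build_for = function(Pn) {
          Pnx <- Pn@x
          function(b) quad_build(qt, list(Pnx), b)
        })
      if (hl$accepted) {
        z <- hl$z
        sigma_u <- exp(hl$lsu)
        sigma_v <- exp(hl$lsv)
      }
      if (it <= mcmc$burnin) {
        scale_hl <- min(max(scale_hl *
          exp(0.05 * ((if (hl$accepted) 1 else 0) - 0.3)), 1e-3), 10)
      }
    }

    if (re) {
      u <- z[p + seq_len(n)]
      v <- z[p + n + seq_len(n)]
      for (sweep in 1:5) {
      uRu <- as.numeric(Matrix::crossprod(u, R %*% u))
      su <- rw_mh_log(log(sigma_u), function(ls) {
        s <- exp(ls)
        -rank_R * ls - uRu / (2 * s^2) +
          log_halfnormal(s, pri$sigma_u_scale) + ls
      }, scale_u, adapt = it <= mcmc$burnin)
      sigma_u <- exp(su$value); scale_u <- su$scale
      vv <- sum(v^2)
      sv <- rw_mh_log(log(sigma_v), function(ls) {
        s <- exp(ls)
        -n * ls - vv / (2 * s^2) + log_halfnormal(s, pri$sigma_v_scale) + ls
      }, scale_v, adapt = it <= mcmc$burnin)
      sigma_v <- exp(sv$value); scale_v <- sv$scale

      # interweaved (non-centred) scale moves: rescale the random-effect
      # vector together with its SD, judged by the Poisson likelihood; this
      # breaks the sticky dependence between the SDs and the latent vectors
      psi_f <- as.numeric(X %*% z[seq_len(p)])
      ll_cur <- pois_ll(psi_f + u + v, offset, O)
      pu <- rw_mh_log(log(sigma_u), function(ls) {
        if (ls == log(sigma_u)) {
          ll_cur + log_halfnormal(sigma_u, pri$sigma_u_scale) + ls
        } else {
          s <- exp(ls)
          pois_ll(psi_f + u * s / sigma_u + v, offset, O) +
            log_halfnormal(s, pri$sigma_u_scale) + ls
        }
      }, scale_u2, adapt = it <= mcmc$burnin)
      if (pu$accepted) {
        u <- u * exp(pu$value) / sigma_u
        sigma_u <- exp(pu$value)
        z[p + seq_len(n)] <- u
        ll_cur <- pois_ll(psi_f + u + v, offset, O)
      }
      scale_u2 <- pu$scale
      pv <- rw_mh_log(log(sigma_v), function(ls) {
        if (ls == log(sigma_v)) {
          ll_cur + log_halfnormal(sigma_v, pri$sigma_v_scale) + ls
        } else {
          s <- exp(ls)
          pois_ll(psi_f + u + v * s / sigma_v, offset, O) +
            log_halfnormal(s, pri$sigma_v_scale) + ls
        }
      }, scale_v2, adapt = it <= mcmc$burnin)
      if (pv$accepted) {
        v <- v * exp(pv$value) / sigma_v
        sigma_v <- exp(pv$value)
        z[p + n + seq_len(n)] <- v
      }
      scale_v2 <- pv$scale
      }
    }

    if (it > mcmc$burnin) {
      k <- it - mcmc$burnin
      keep_cf[k, ] <- z[seq_len(p)]
      keep_sig[k, ] <- c(sigma_u, sigma_v)
      lam <- exp(as.numeric(Mmat %*% z))     # relative risk, no offset
      lam_sum <- lam_sum + lam
      lam_ssq <- lam_ssq + lam^2
      if (k %% mcmc$thin == 0) {
        kd <- kd + 1
        lam_draws[kd, ] <- lam
      }
    }
  }

  fit_result(keep_cf, keep_sig, lam_draws[seq_len(kd), , drop = FALSE],
             acc_lat / mcmc$n_iter, spec, des$qc, areas$id, re)
}

# Assemble a bym_fit object from kept draws.
fit_result <- function(keep_cf, keep_sig, lam_draws, acc_rate, spec, qc,
                       area_ids, re) {
  p <- ncol(keep_cf)
  summ <- data.frame(parameter = colnames(keep_cf),
                     t(apply(keep_cf, 2, summarise_draws)))
  names(summ) <- c("parameter", "mean", "q2.5", "median", "q97.5")
  is_rr <- grepl("^rr_", summ$parameter)
  rr <- summ[is_rr, , drop = FALSE]
  if (nrow(rr) > 0) {
    rr[, c("mean", "q2.5", "median", "q97.5")] <-
      exp(rr[, c("mean", "q2.5", "median", "q97.5")])
    rr$significant <- vapply(seq_len(nrow(rr)), function(i) {
      significance_flag(rr[i, ])
    }, logical(1))
  }
  diag_tab <- data.frame(
    parameter = c(colnames(keep_cf), if (re) colnames(keep_sig)),
    rhat = c(apply(keep_cf, 2, split_rhat),
             if (re) apply(keep_sig, 2, split_rhat)),
    ess = c(apply(keep_cf, 2, ess), if (re) apply(keep_sig, 2, ess)))
  flagged <- any(diag_tab$rhat > 1.05, na.rm = TRUE)
  if (flagged) {
    warning("possible non-convergence: max split R-hat = ",
            round(max(diag_tab$rhat, na.rm = TRUE), 3), "; fit flagged")
  }
  lam_mean <- colMeans(lam_draws)
  lam_q <- t(apply(lam_draws, 2, quantile, c(0.025, 0.975), type = 7))
  structure(list(
    summary = summ, rr_table = rr,
    sigma_summary = if (re) {
      data.frame(parameter = colnames(keep_sig),
                 t(apply(keep_sig, 2, summarise_draws)))
    },
    lambda = data.frame(area_id = area_ids, rr_mean = lam_mean,
                        rr_q2.5 = lam_q[, 1], rr_q97.5 = lam_q[, 2]),
    quartiles = qc,
    draws = list(coef = keep_cf, sigma = keep_sig),
    diagnostics = diag_tab, accept_rate = acc_rate,
    spec = spec, flagged = flagged),
    class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("Poisson BYM ecological fit (", x$spec$coding, ")\n", sep = "")
  if (nrow(x$rr_table) > 0) {
    tab <- x$rr_table
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-10s RR %.3f (95%% CI %.3f-%.3f)%s\n",
                  tab$parameter[i], tab$mean[i], tab$q2.5[i], tab$q97.5[i],
                  if (tab$significant[i]) " *" else ""))
    }
  }
  if (!is.null(x$sigma_summary)) {
    cat(sprintf("  sigma_u %.3f, sigma_v %.3f\n",
                x$sigma_summary$mean[1], x$sigma_summary$mean[2]))
  }
  cat(sprintf("  latent acceptance %.2f; max R-hat %.3f%s\n", x$accept_rate,
              max(x$diagnostics$rhat, na.rm = TRUE),
              if (x$flagged) " (FLAGGED)" else ""))
  invisible(x)
}

#' Trend test: quartile ordinal as a continuous covariate
#'
#' Refits the BYM regression with the exposure quartile ordinal (1-4) entered
#' as a continuous variable; the reported RR is per one-quartile increment.
#'
#' @inheritParams fit_bym
#' @return a `bym_fit` whose `rr_table` holds the per-quartile-step RR.
#' @export
trend_test <- function(areas, edges, observed, expected, spec = bym_spec(),
                       mcmc = mcmc_config()) {
  spec$coding <- "quartile_ordinal"
  fit_bym(areas, edges, observed, expected, spec, mcmc)
}

#' Is a relative risk statistically significant at the 95% level?
#'
#' TRUE iff the 95% credibility interval strictly excludes 1 (an interval
#' exactly touching 1 at either end is not significant).
#'
#' @param rr_summary list/row with `q2.5` and `q97.5` on the RR scale.
#' @return logical.
#' @export
significance_flag <- function(rr_summary) {
  lo <- rr_summary$q2.5
  hi <- rr_summary$q97.5
  stopifnot(is.finite(lo), is.finite(hi), lo <= hi)
  lo > 1 || hi < 1
}

#' Smoothed relative-risk map table
#'
#' Joins per-area posterior-mean relative risks to the areas table and
#' assigns quantile classes (quartiles or quintiles) for choropleth export.
#'
#' @param fit a `bym_fit` (or `joint_fit`).
#' @param areas areas data frame.
#' @param classes `"quartile"` or `"quintile"`.
#' @return areas with `rr_mean`, `rr_q2.5`, `rr_q97.5`, `rr_class` columns.
#' @export
smoothed_risk_map <- function(fit, areas, classes = c("quartile", "quintile")) {
  classes <- match.arg(classes)
  if (isTRUE(fit$flagged)) {
    warning("fit was flagged for possible non-convergence")
  }
  lam <- fit$lambda
  idx <- match(areas$id, lam$area_id)
  if (anyNA(idx)) stop("fit does not cover all areas")
  areas$rr_mean <- lam$rr_mean[idx]
  areas$rr_q2.5 <- lam$rr_q2.5[idx]
  areas$rr_q97.5 <- lam$rr_q97.5[idx]
  k <- if (classes == "quartile") 4L else 5L
  br <- unique(quantile(areas$rr_mean, seq(0, 1, length.out = k + 1),
                        type = 7))
  cl <- cut(areas$rr_mean, br, include.lowest = TRUE,
            labels = paste0("c", seq_len(length(br) - 1)))
  areas$rr_class <- as.character(cl)
  areas
}
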