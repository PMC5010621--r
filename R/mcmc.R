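#' MCMC configuration
#'
#' @param n_iter kept iterations after burn-in.
#' @param burnin burn-in iterations (adaptation of scalar proposal scales
#'   happens only here, so the kept chain is a fixed-kernel Markov chain).
#' @param thin thinning interval for stored latent-field draws.
#' @param seed integer seed; chains are reproducible given `(data, config)`.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 800, burnin = 400, thin = 1, seed = 1L) {
  stopifnot(n_iter >= 10, burnin >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Prior configuration for the disease and field models
#'
#' Fixed effects get independent Normal(0, `fixed_sd`^2) priors; the BYM
#' standard deviations half-Normal(0, scale^2); the measurement-error SD
#' half-Normal; the Matern field hyperparameters penalised-complexity-style
#' priors: `P(range < range0) = alpha_range` and
#' `P(sigma > sigma0) = alpha_sigma`.
#'
#' @param fixed_sd prior SD of fixed effects (default 10).
#' @param sigma_u_scale,sigma_v_scale half-Normal scales of the BYM SDs.
#' @param sigma_x_scale half-Normal scale of the measurement-error SD.
#' @param range0,alpha_range,sigma0,alpha_sigma PC-prior anchors for the
#'   field's practical range (km) and marginal SD.
#' @return a `prior_config` list.
#' @export
prior_config <- function(fixed_sd = 10, sigma_u_scale = 1, sigma_v_scale = 1,
                         sigma_x_scale = 1, range0 = 10, alpha_range = 0.05,
                         sigma0 = 2, alpha_sigma = 0.05) {
  structure(list(fixed_sd = fixed_sd, sigma_u_scale = sigma_u_scale,
                 sigma_v_scale = sigma_v_scale, sigma_x_scale = sigma_x_scale,
                 range0 = range0, alpha_range = alpha_range,
                 sigma0 = sigma0, alpha_sigma = alpha_sigma),
            class = "prior_config")
}

log_halfnormal <- function(x, scale) {
  ifelse(x <= 0, -Inf, dnorm(x, 0, scale, log = TRUE) + log(2))
}

# PC prior log-densities on the log scale (Jacobian included).
log_pc_range <- function(log_rho, range0, alpha) {
  lam <- -range0 * log(alpha)
  rho <- exp(log_rho)
  log(lam) - 2 * log_rho - lam / rho + log_rho
}

log_pc_sigma <- function(log_sigma, sigma0, alpha) {
  lam <- -log(alpha) / sigma0
  sig <- exp(log_sigma)
  log(lam) - lam * sig + log_sigma
}

# Poisson log-likelihood for linear predictor psi with log-offset.
pois_ll <- function(psi, offset, O) {
  eta <- offset + psi
  sum(O * eta - exp(eta))
}

# One Metropolis-Hastings update of a Gaussian latent block z under
#   prior/Gaussian-likelihood part: exp(-z' P z / 2 + blin' z)
#   Poisson likelihood: O ~ Pois(exp(offset + M z))
# using an independence proposal: the Gaussian (Laplace) approximation of the
# full conditional, built by a second-order Taylor expansion of the Poisson
# term at the conditional mode. The mode is tracked across iterations by
# Newton steps in `mode_env$z_hat`; it depends only on the data and the
# current hyperparameters (never on the current state), so the proposal is a
# valid independence kernel. Optional linear constraints A z = 0 are enforced
# by conditioning the Gaussian by kriging; densities are then conditional
# densities on the constraint subspace. For log-concave Poisson likelihoods
# the approximation is close to the target and acceptance rates are high.
#
# Returns list(z, accepted).
gmrf_mh_step <- function(z, P, blin, M, offset, O, A = NULL,
                         mode_env, newton_tol = 1e-3, max_newton = 30,
                         Qc_build = NULL, adapt = FALSE, local_stage = TRUE) {
  # Newton iteration to the (unique, log-concave) conditional mode, warm
  # started from the previous iteration's mode; run to convergence so the
  # proposal is a function of the conditioning blocks only
  for (k in seq_len(max_newton)) {
    ga <- gaussian_approx(mode_env$z_hat, P, blin, M, offset, O, mode_env,
                          Qc_build)
    if (is.null(ga)) return(list(z = z, accepted = FALSE))
    m <- ga$mean
    if (!is.null(A)) m <- constraint_correct(m, ga$ch, A)$z
    delta <- max(abs(m - mode_env$z_hat))
    mode_env$z_hat <- m
    if (delta < newton_tol) break
  }
  ga <- gaussian_approx(mode_env$z_hat, P, blin, M, offset, O, mode_env,
                        Qc_build)
  if (is.null(ga)) return(list(z = z, accepted = FALSE))
  mode_env$ga <- ga

  eps <- rnorm(length(z))
  y <- Matrix::solve(ga$ch, eps, system = "Lt")
  z_new <- ga$mean + as.numeric(Matrix::solve(ga$ch, y, system = "Pt"))
  if (!is.null(A)) {
    z_new <- constraint_correct(z_new, ga$ch, A)$z
    log_q_new <- gauss_logdens_constrained(z_new, ga, A)
    log_q_old <- gauss_logdens_constrained(z, ga, A)
  } else {
    log_q_new <- gauss_logdens(z_new, ga)
    log_q_old <- gauss_logdens(z, ga)
  }
  lt_z <- function(zz) {
    pois_ll(as.numeric(M %*% zz), offset, O) - 0.5 * quad_form(zz, P) +
      sum(blin * zz)
  }
  log_alpha <- (lt_z(z_new) - lt_z(z)) + (log_q_old - log_q_new)
  accepted <- is.finite(log_alpha) && log(runif(1)) < log_alpha
  if (accepted) z <- z_new

  # second stage: a state-centred autoregressive move. From the Taylor
  # expansion at the current state, step a fraction gamma toward its
  # (constrained) mean and add matched noise,
  #   z* = (1 - gamma) z + gamma m(z) + sqrt(gamma (2 - gamma)) eps,
  # with the reverse density from the expansion at z*. For an exactly
  # Gaussian conditional this proposal is in detailed balance for any
  # gamma; for the Poisson conditional the step size is adapted during
  # burn-in. The independence kernel mixes fast near the conditional mode;
  # this local kernel keeps the block tracking its conditional when other
  # blocks or hyperparameters have moved it off-mode, so the chain cannot
  # freeze.
  if (!local_stage) return(list(z = z, accepted = accepted))
  gam <- if (is.null(mode_env$gamma)) 0.5 else mode_env$gamma
  s2 <- gam * (2 - gam)
  acc2 <- FALSE
  ga_loc <- gaussian_approx(z, P, blin, M, offset, O, mode_env, Qc_build)
  if (!is.null(ga_loc)) {
    m_c <- ga_loc$mean
    if (!is.null(A)) m_c <- constraint_correct(m_c, ga_loc$ch, A)$z
    eps <- rnorm(length(z))
    y0 <- Matrix::solve(ga_loc$ch, eps, system = "Lt")
    x0 <- as.numeric(Matrix::solve(ga_loc$ch, y0, system = "Pt"))
    if (!is.null(A)) x0 <- constraint_correct(x0, ga_loc$ch, A)$z
    mu_f <- (1 - gam) * z + gam * m_c
    z_prop <- mu_f + sqrt(s2) * x0
    lq_f <- local_logq(z_prop, ga_loc, A, mu_f, s2)
    ga_rev <- gaussian_approx(z_prop, P, blin, M, offset, O, mode_env,
                              Qc_build)
    if (!is.null(ga_rev)) {
      m_cr <- ga_rev$mean
      if (!is.null(A)) m_cr <- constraint_correct(m_cr, ga_rev$ch, A)$z
      mu_r <- (1 - gam) * z_prop + gam * m_cr
      lq_r <- local_logq(z, ga_rev, A, mu_r, s2)
      la2 <- (lt_z(z_prop) - lt_z(z)) + (lq_r - lq_f)
      if (is.finite(la2) && log(runif(1)) < la2) {
        z <- z_prop
        accepted <- TRUE
        acc2 <- TRUE
      }
    }
  }
  if (adapt) {
    gam <- gam * exp(0.08 * ((if (acc2) 1 else 0) - 0.4))
    mode_env$gamma <- min(max(gam, 0.02), 1)
  }
  list(z = z, accepted = accepted)
}

# log-density of N(mu, s2 * Q^{-1}) (optionally conditioned on A z = 0)
# evaluated at z_eval, up to constants that cancel between the forward and
# reverse proposals of the autoregressive local move.
local_logq <- function(z_eval, ga, A, mu, s2) {
  v <- z_eval - mu
  base <- 0.5 * ga$logdet - 0.5 * quad_form(v, ga$Q) / s2
  if (!is.null(A)) {
    W <- Matrix::solve(ga$ch, Matrix::t(A), system = "A")
    S <- as.matrix(A %*% W)
    am <- as.numeric(A %*% mu)
    base <- base + 0.5 * determinant(S, logarithm = TRUE)$modulus +
      0.5 * sum(am * solve(S, am)) / s2
  }
  base
}

quad_form <- function(z, P) as.numeric(Matrix::crossprod(z, P %*% z))

to_dgc <- function(M) {
  as(as(as(M, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# Precompute a symmetric sparse template for the BYM prior precision
#   P(sigma_u, sigma_v) = blockdiag(D_fixed, R / sigma_u^2 (+ stiff diagonal
#   for isolated areas), I / sigma_v^2)
# so the per-iteration update is pure arithmetic on the x slot.
bym_prior_template <- function(p, n, R, iso, fixed_sd) {
  Rt <- as(to_dgc(R), "TsparseMatrix")
  keep <- Rt@i <= Rt@j
  ti <- c(seq_len(p), p + Rt@i[keep] + 1L, p + which(iso),
          p + n + seq_len(n))
  tj <- c(seq_len(p), p + Rt@j[keep] + 1L, p + which(iso),
          p + n + seq_len(n))
  xf <- c(rep(1 / fixed_sd^2, p), numeric(sum(keep)),
          rep(1e6, sum(iso)), numeric(n))
  xR <- c(numeric(p), Rt@x[keep], numeric(sum(iso)), numeric(n))
  xv <- c(numeric(p + sum(keep) + sum(iso)), rep(1, n))
  key <- paste(ti, tj)
  if (anyDuplicated(key)) {
    agg_f <- rowsum(xf, key); agg_R <- rowsum(xR, key); agg_v <- rowsum(xv, key)
    ij <- do.call(rbind, strsplit(rownames(agg_f), " "))
    ti <- as.integer(ij[, 1]); tj <- as.integer(ij[, 2])
    xf <- as.numeric(agg_f); xR <- as.numeric(agg_R); xv <- as.numeric(agg_v)
  }
  dim_z <- p + 2L * n
  Midx <- Matrix::sparseMatrix(i = ti, j = tj, x = seq_along(ti),
                               dims = c(dim_z, dim_z), symmetric = TRUE)
  ord <- Midx@x
  Pm <- Midx
  list(Pm = Pm, xf = xf[ord], xR = xR[ord], xv = xv[ord])
}

bym_prior_precision <- function(tmpl, sigma_u, sigma_v) {
  P <- tmpl$Pm
  P@x <- tmpl$xf + tmpl$xR / sigma_u^2 + tmpl$xv / sigma_v^2
  P
}

gaussian_approx <- function(z0, P, blin, M, offset, O, cache = NULL,
                            Qc_build = NULL) {
  psi0 <- as.numeric(M %*% z0)
  mu0 <- exp(offset + psi0)
  b <- pmin(mu0, 1e8)
  Qc <- if (!is.null(Qc_build)) {
    Qc_build(b)
  } else {
    bM <- M
    bM@x <- M@x * b[M@i + 1L]   # diag(b) %*% M without dispatch overhead
    Matrix::forceSymmetric(P + Matrix::crossprod(M, bM))
  }
  # reuse the symbolic factorisation: the sparsity pattern is constant
  # across iterations of a sampler
  ch <- tryCatch({
    if (!is.null(cache) && !is.null(cache$sym)) {
      update(cache$sym, Qc)
    } else {
      f <- Matrix::Cholesky(Qc, LDL = FALSE, perm = TRUE)
      if (!is.null(cache)) cache$sym <- f
      f
    }
  }, error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  lin <- blin + as.numeric(Matrix::crossprod(M, (O - mu0) + b * psi0))
  m <- as.numeric(Matrix::solve(ch, lin, system = "A"))
  list(mean = m, Q = Qc, ch = ch,
       logdet = 2 * Matrix::determinant(ch, logarithm = TRUE,
                                        sqrt = TRUE)$modulus)
}

gauss_logdens <- function(z, ga) {
  as.numeric(0.5 * ga$logdet - 0.5 * quad_form(z - ga$mean, ga$Q))
}

# Correct a draw onto {A z = 0} by conditioning by kriging.
constraint_correct <- function(z, ch, A) {
  W <- Matrix::solve(ch, Matrix::t(A), system = "A")   # Q^{-1} A'
  S <- as.matrix(A %*% W)                              # A Q^{-1} A'
  adj <- W %*% solve(S, as.numeric(A %*% z))
  list(z = z - as.numeric(adj), W = W, S = S)
}

# Density of the Gaussian approximation conditioned on A z = 0, evaluated at
# a point satisfying the constraint:
#   log N(z; m, Q^{-1}) - log N(0; A m, A Q^{-1} A')   (+ constants that
# cancel between forward and reverse proposals of equal dimension).
gauss_logdens_constrained <- function(z, ga, A) {
  W <- Matrix::solve(ga$ch, Matrix::t(A), system = "A")
  S <- as.matrix(A %*% W)
  am <- as.numeric(A %*% ga$mean)
  gauss_logdens(z, ga) +
    0.5 * determinant(S, logarithm = TRUE)$modulus +
    0.5 * sum(am * solve(S, am))
}

# Adaptive scalar random-walk MH on a log-scale parameter. `logtarget` takes
# the log-parameter. Returns list(value, scale, accepted).
rw_mh_log <- function(log_x, logtarget, scale, adapt = FALSE, target_acc = 0.44) {
  prop <- log_x + rnorm(1, 0, scale)
  la <- logtarget(prop) - logtarget(log_x)
  acc <- is.finite(la) && log(runif(1)) < la
  if (acc) log_x <- prop
  if (adapt) {
    scale <- scale * exp(0.05 * ((if (acc) 1 else 0) - target_acc))
    scale <- min(max(scale, 1e-3), 10)
  }
  list(value = log_x, scale = scale, accepted = acc)
}

# Draw from a (possibly constrained) Gaussian approximation; returns the
# draw and its proposal log-density.
gauss_propose <- function(ga, A) {
  eps <- rnorm(length(ga$mean))
  y <- Matrix::solve(ga$ch, eps, system = "Lt")
  z_new <- ga$mean + as.numeric(Matrix::solve(ga$ch, y, system = "Pt"))
  if (!is.null(A)) {
    z_new <- constraint_correct(z_new, ga$ch, A)$z
    list(z = z_new, log_q = gauss_logdens_constrained(z_new, ga, A))
  } else {
    list(z = z_new, log_q = gauss_logdens(z_new, ga))
  }
}

# Joint update of the BYM variance parameters and the whole latent block
# ("one-block" move): propose (log sigma_u, log sigma_v) by a random walk,
# rebuild the Laplace approximation of the latent conditional under the
# proposed values, draw the latent block from it, and accept everything
# together. This decouples the SD chains from the latent vector and is the
# main mixing device for sigma_u / sigma_v; the Laplace approximation of the
# current state (ga_cur, from the preceding latent update) supplies the
# reverse proposal density.
#
# P_build(sigma_u, sigma_v) -> prior precision; log-prior normalisation
# (rank_R/2) log tau_u + (n/2) log tau_v is handled here.
hyper_latent_step <- function(z, lsu, lsv, P_build, blin, M, offset, O, A,
                              rank_R, n, pri, scale, mode_env, Qc_build_for) {
  ga_cur <- mode_env$ga
  if (is.null(ga_cur)) return(list(lsu = lsu, lsv = lsv, z = z,
                                   accepted = FALSE))
  prop <- c(lsu, lsv) + rnorm(2, 0, scale)
  P_new <- P_build(exp(prop[1]), exp(prop[2]))
  qb <- Qc_build_for(P_new)
  z_hat_save <- mode_env$z_hat
  ga_save <- ga_cur
  st_env <- new.env()
  st_env$z_hat <- mode_env$z_hat
  ga_new <- NULL
  for (k in 1:30) {
    ga_new <- gaussian_approx(st_env$z_hat, P_new, blin, M, offset, O,
                              mode_env, qb)
    if (is.null(ga_new)) break
    m <- ga_new$mean
    if (!is.null(A)) m <- constraint_correct(m, ga_new$ch, A)$z
    delta <- max(abs(m - st_env$z_hat))
    st_env$z_hat <- m
    if (delta < 1e-3) break
  }
  if (is.null(ga_new)) {
    return(list(lsu = lsu, lsv = lsv, z = z, accepted = FALSE))
  }
  ga_new <- gaussian_approx(st_env$z_hat, P_new, blin, M, offset, O,
                            mode_env, qb)
  if (is.null(ga_new)) {
    return(list(lsu = lsu, lsv = lsv, z = z, accepted = FALSE))
  }
  pr <- gauss_propose(ga_new, A)
  z_new <- pr$z
  log_q_new <- pr$log_q
  log_q_old <- if (!is.null(A)) gauss_logdens_constrained(z, ga_cur, A)
               else gauss_logdens(z, ga_cur)
  P_old <- P_build(exp(lsu), exp(lsv))
  lt <- function(zz, P, su_l, sv_l) {
    pois_ll(as.numeric(M %*% zz), offset, O) - 0.5 * quad_form(zz, P) +
      sum(blin * zz) -
      rank_R * su_l - n * sv_l +
      log_halfnormal(exp(su_l), pri$sigma_u_scale) + su_l +
      log_halfnormal(exp(sv_l), pri$sigma_v_scale) + sv_l
  }
  log_alpha <- lt(z_new, P_new, prop[1], prop[2]) -
    lt(z, P_old, lsu, lsv) + log_q_old - log_q_new
  if (is.finite(log_alpha) && log(runif(1)) < log_alpha) {
    mode_env$z_hat <- st_env$z_hat
    mode_env$ga <- ga_new
    list(lsu = prop[1], lsv = prop[2], z = z_new, accepted = TRUE)
  } else {
    mode_env$z_hat <- z_hat_save
    mode_env$ga <- ga_save
    list(lsu = lsu, lsv = lsv, z = z, accepted = FALSE)
  }
}

# Initialise a latent block at a draw from the Laplace approximation of its
# full conditional (Newton from z0 to the mode, then one Gaussian draw).
# Starting the chain inside the typical set of the independence proposal
# avoids an astronomically over-weighted initial state.
laplace_init <- function(z0, P, blin, M, offset, O, A, mode_env, Qc_build) {
  mode_env$z_hat <- z0
  for (k in 1:50) {
    ga <- gaussian_approx(mode_env$z_hat, P, blin, M, offset, O, mode_env,
                          Qc_build)
    if (is.null(ga)) return(z0)
    m <- ga$mean
    if (!is.null(A)) m <- constraint_correct(m, ga$ch, A)$z
    delta <- max(abs(m - mode_env$z_hat))
    mode_env$z_hat <- m
    if (delta < 1e-6) break
  }
  ga <- gaussian_approx(mode_env$z_hat, P, blin, M, offset, O, mode_env,
                        Qc_build)
  if (is.null(ga)) return(mode_env$z_hat)
  gauss_propose(ga, A)$z
}
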