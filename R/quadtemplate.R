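# Fast assembly of conditional precision matrices
#
#   Qc = sum_k P_k  +  M' diag(b) M  (+ explicitly supplied extra entries)
#
# for samplers whose sparsity pattern is fixed across iterations. The union
# pattern is computed once; each iteration then fills the x slot of a cached
# symmetric template by vector arithmetic: the product term is K %*% b where
# K maps observation weights to stored entries, and each P_k's x slot is
# scattered through a precomputed index map. This avoids the (expensive)
# generic sparse add/coerce path in the hot loop.

# M: dgCMatrix design (rows = Poisson observations). priors: list of dsC
# matrices fixing the prior patterns (values irrelevant here). extra_coords:
# optional 2-column matrix (row <= col) of entries whose values are supplied
# directly at build time (used for design columns whose values change).
quad_template <- function(M, priors, extra_coords = NULL) {
  dim_z <- ncol(M)
  Tm <- as(M, "TsparseMatrix")
  ro <- Tm@i + 1L
  co <- Tm@j + 1L
  xs <- Tm@x
  ordr <- order(ro, co)
  ro <- ro[ordr]; co <- co[ordr]; xs <- xs[ordr]
  # upper-triangle products per observation row
  starts <- c(1L, which(diff(ro) > 0) + 1L, length(ro) + 1L)
  pi_ <- pj_ <- pobs <- pval <- vector("list", length(starts) - 1L)
  for (r in seq_len(length(starts) - 1L)) {
    sel <- starts[r]:(starts[r + 1L] - 1L)
    J <- co[sel]; W <- xs[sel]
    k <- length(J)
    ia <- rep(seq_len(k), k)
    ib <- rep(seq_len(k), each = k)
    keep <- ia <= ib
    ia <- ia[keep]; ib <- ib[keep]
    val <- W[ia] * W[ib]
    nz <- val != 0
    pi_[[r]] <- J[ia][nz]; pj_[[r]] <- J[ib][nz]
    pobs[[r]] <- rep(ro[sel[1]], sum(nz)); pval[[r]] <- val[nz]
  }
  pi_ <- unlist(pi_); pj_ <- unlist(pj_)
  pobs <- unlist(pobs); pval <- unlist(pval)

  prior_trip <- lapply(priors, function(P) {
    Pt <- as(P, "TsparseMatrix")   # dsT: upper or lower storage
    i <- Pt@i + 1L; j <- Pt@j + 1L
    cbind(pmin(i, j), pmax(i, j))
  })
  ex <- if (!is.null(extra_coords)) {
    cbind(pmin(extra_coords[, 1], extra_coords[, 2]),
          pmax(extra_coords[, 1], extra_coords[, 2]))
  }
  all_i <- c(pi_, unlist(lapply(prior_trip, function(t) t[, 1])),
             if (!is.null(ex)) ex[, 1])
  all_j <- c(pj_, unlist(lapply(prior_trip, function(t) t[, 2])),
             if (!is.null(ex)) ex[, 2])
  key <- (as.numeric(all_i) - 1) * dim_z + all_j
  ukey <- sort(unique(key))
  ui <- as.integer((ukey - 1) %/% dim_z + 1)
  uj <- as.integer((ukey - 1) %% dim_z + 1)
  nU <- length(ukey)
  Tmpl <- Matrix::sparseMatrix(i = ui, j = uj, x = seq_len(nU),
                               dims = c(dim_z, dim_z), symmetric = TRUE)
  sp <- integer(nU)
  sp[as.integer(Tmpl@x)] <- seq_len(nU)   # unique-index -> storage position
  pos_of <- function(i, j) sp[match((as.numeric(i) - 1) * dim_z + j, ukey)]

  K <- Matrix::sparseMatrix(i = pos_of(pi_, pj_), j = pobs, x = pval,
                            dims = c(nU, nrow(M)))
  prior_maps <- lapply(seq_along(priors), function(k) {
    tt <- prior_trip[[k]]
    pos_of(tt[, 1], tt[, 2])
  })
  extra_map <- if (!is.null(ex)) pos_of(ex[, 1], ex[, 2])
  Tmpl@x <- numeric(nU)
  list(Tmpl = Tmpl, K = K, prior_maps = prior_maps, extra_map = extra_map,
       nU = nU)
}

# Assemble Qc from the template: prior_xs is a list of @x vectors aligned
# with the priors given to quad_template; b the Poisson weights (possibly
# pre-scaled); extra_vals values for extra_coords (same order).
quad_build <- function(qt, prior_xs, b, extra_vals = NULL) {
  x <- as.numeric(qt$K %*% b)
  for (k in seq_along(prior_xs)) {
    m <- qt$prior_maps[[k]]
    x[m] <- x[m] + prior_xs[[k]]
  }
  if (!is.null(extra_vals)) {
    m <- qt$extra_map
    x[m] <- x[m] + extra_vals
  }
  Q <- qt$Tmpl
  Q@x <- x
  Q
}

# Template for fast weighted sums of symmetric sparse matrices with a fixed
# joint pattern: sum_k w_k * mats[[k]]. Used for per-iteration SPDE precision
# assembly Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G).
sym_sum_template <- function(mats) {
  dim_z <- nrow(mats[[1]])
  trips <- lapply(mats, function(P) {
    Pt <- as(P, "TsparseMatrix")
    list(i = pmin(Pt@i, Pt@j) + 1L, j = pmax(Pt@i, Pt@j) + 1L, x = Pt@x)
  })
  all_i <- unlist(lapply(trips, `[[`, "i"))
  all_j <- unlist(lapply(trips, `[[`, "j"))
  key <- (as.numeric(all_i) - 1) * dim_z + all_j
  ukey <- sort(unique(key))
  nU <- length(ukey)
  Tmpl <- Matrix::sparseMatrix(
    i = as.integer((ukey - 1) %/% dim_z + 1),
    j = as.integer((ukey - 1) %% dim_z + 1),
    x = seq_len(nU), dims = c(dim_z, dim_z), symmetric = TRUE)
  sp <- integer(nU)
  sp[as.integer(Tmpl@x)] <- seq_len(nU)
  xs <- lapply(trips, function(t) {
    v <- numeric(nU)
    pos <- sp[match((as.numeric(t$i) - 1) * dim_z + t$j, ukey)]
    agg <- rowsum(t$x, pos)          # duplicates within one matrix summed
    v[as.integer(rownames(agg))] <- as.numeric(agg)
    v
  })
  Tmpl@x <- numeric(nU)
  list(Tmpl = Tmpl, xs = xs)
}

sym_sum_build <- function(st, w) {
  x <- numeric(length(st$xs[[1]]))
  for (k in seq_along(w)) x <- x + w[k] * st$xs[[k]]
  Q <- st$Tmpl
  Q@x <- x
  Q
}
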