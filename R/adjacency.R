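#' Rook adjacency for a regular grid of areas
#'
#' @param nx,ny grid dimensions.
#' @return two-column integer matrix of undirected edges (i < j), 1-based
#'   indices in row-major order (x fastest).
#' @export
grid_adjacency <- function(nx, ny) {
  stopifnot(nx >= 1, ny >= 1)
  idx <- function(ix, iy) (iy - 1L) * nx + ix
  e <- list()
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      if (ix < nx) e[[length(e) + 1L]] <- c(idx(ix, iy), idx(ix + 1L, iy))
      if (iy < ny) e[[length(e) + 1L]] <- c(idx(ix, iy), idx(ix, iy + 1L))
    }
  }
  m <- do.call(rbind, e)
  storage.mode(m) <- "integer"
  colnames(m) <- c("i", "j")
  m
}

# Validate an edge list: symmetric by construction (stored i < j), irreflexive.
check_edges <- function(edges, n) {
  edges <- as.matrix(edges)
  stopifnot(ncol(edges) == 2)
  if (any(edges[, 1] == edges[, 2])) stop("adjacency must be irreflexive")
  if (any(edges < 1) || any(edges > n)) stop("edge index out of range")
  t(apply(edges, 1, sort))
}

#' ICAR structure matrix (graph Laplacian) from an edge list
#'
#' Builds the sparse structure matrix `R = D - W` of the intrinsic conditional
#' autoregressive prior, where `W` is the binary adjacency matrix and `D` the
#' diagonal of neighbour counts. `R` is singular with one null vector
#' (constant) per connected component; the ICAR prior therefore carries a
#' sum-to-zero constraint per component.
#'
#' @param edges two-column matrix of undirected edges.
#' @param n number of areas.
#' @return sparse symmetric `n x n` Matrix.
#' @export
icar_structure <- function(edges, n) {
  edges <- check_edges(edges, n)
  W <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

# Connected components of the adjacency graph (integer labels 1..K),
# by iterative label propagation (graphs here are a few hundred nodes).
graph_components <- function(edges, n) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[a] <- m; comp[b] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

#' Draw from the intrinsic CAR prior under sum-to-zero constraints
#'
#' Samples `u` with density proportional to
#' \eqn{\exp\{-u^T R u / (2\sigma_u^2)\}} restricted to sum to zero within
#' each connected component, via the spectral decomposition of `R` (null
#' eigenvectors dropped). Isolated areas (no neighbours) get `u = 0`; the
#' unstructured effect covers them.
#'
#' @param edges undirected edge list.
#' @param n number of areas.
#' @param sigma_u conditional standard deviation scale (> 0).
#' @param seed integer seed.
#' @return list with `u` (length-n vector summing to zero per component) and
#'   `components` (component labels).
#' @export
simulate_icar <- function(edges, n, sigma_u, seed) {
  stopifnot(sigma_u > 0)
  R <- as.matrix(icar_structure(edges, n))
  eg <- eigen(R, symmetric = TRUE)
  tol <- 1e-8 * max(eg$values)
  pos <- eg$values > tol
  z <- with_seed(seed, rnorm(sum(pos)))
  u <- drop(eg$vectors[, pos, drop = FALSE] %*% (z * sigma_u / sqrt(eg$values[pos])))
  comp <- graph_components(check_edges(edges, n), n)
  # exact re-centring per component absorbs numerical eigen round-off
  for (k in unique(comp)) {
    sel <- comp == k
    u[sel] <- u[sel] - mean(u[sel])
  }
  list(u = u, components = comp)
}
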