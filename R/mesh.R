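# --- geometry helpers -------------------------------------------------------

# Accept either c(xmin, xmax, ymin, ymax) or a polygon vertex matrix; return
# the polygon (closed implicitly) and its bounding box.
normalise_domain <- function(domain) {
  if (is.numeric(domain) && length(domain) == 4) {
    poly <- cbind(x = domain[c(1, 2, 2, 1)], y = domain[c(3, 3, 4, 4)])
  } else {
    poly <- as.matrix(domain)
    stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
    if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), ]
    if (polygon_self_intersects(poly)) {
      stop("domain polygon is self-intersecting")
    }
  }
  list(polygon = poly,
       bbox = c(range(poly[, 1]), range(poly[, 2])))
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (segments_cross(poly[i, ], poly[i %% n + 1, ],
                         poly[j, ], poly[j %% n + 1, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Even-odd ray casting, boundary-inclusive within tolerance.
point_in_polygon <- function(pts, poly, tol = 1e-9) {
  n <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # boundary points
    seg_len2 <- (xj - xi)^2 + (yj - yi)^2
    if (seg_len2 > 0) {
      t <- pmin(1, pmax(0, ((px - xi) * (xj - xi) + (py - yi) * (yj - yi)) /
                          seg_len2))
      d2 <- (px - (xi + t * (xj - xi)))^2 + (py - (yi + t * (yj - yi)))^2
      inside <- inside | (d2 <= tol^2)
    }
  }
  inside
}

# --- mesh construction ------------------------------------------------------

# Grid breakpoints along one axis: uniform spacing <= h_int inside [a, b],
# geometrically coarsening steps (<= h_ext) over the extension.
axis_breaks <- function(a, b, h_int, ext_width, h_ext, grow = 1.5) {
  ncell <- max(1L, ceiling((b - a) / h_int))
  inner <- seq(a, b, length.out = ncell + 1)
  offs <- numeric(0)
  if (ext_width > 0) {
    step <- min(h_int, h_ext)
    total <- 0
    while (total < ext_width) {
      step <- min(step, h_ext)
      offs <- c(offs, total + step)
      total <- total + step
      step <- step * grow
    }
  }
  c(a - rev(offs), inner, b + offs)
}

#' Build a graded triangulated mesh over a domain with a boundary extension
#'
#' Constructs a conforming triangulation from a tensor-product grid: uniform
#' cells inside the domain's bounding box sized so that every interior edge
#' (including cell diagonals) is at most `max_edge_interior`, surrounded by a
#' ring of geometrically coarsening cells of total width `extension_width`
#' whose edges are bounded by `max_edge_exterior`. Each rectangular cell is
#' split into two triangles along the same diagonal, so the mesh is fully
#' deterministic. The extension controls boundary effects of the SPDE
#' approximation.
#'
#' @param domain either `c(xmin, xmax, ymin, ymax)` or a simple polygon vertex
#'   matrix (meshed via its bounding box; vertices are classified against the
#'   polygon itself).
#' @param max_edge_interior maximum edge length inside the domain (km, > 0).
#' @param extension_width width of the coarser boundary ring (km, >= 0).
#' @param max_edge_exterior maximum edge length in the ring
#'   (>= `max_edge_interior`).
#' @return object of class `spde_mesh`: `vertices` (n x 2), `triangles`
#'   (m x 3, counter-clockwise), `interior_mask`, axis breakpoints `xs`, `ys`,
#'   and the build parameters.
#' @export
build_mesh <- function(domain, max_edge_interior, extension_width = 0,
                       max_edge_exterior = max_edge_interior) {
  stopifnot(max_edge_interior > 0, extension_width >= 0,
            max_edge_exterior >= max_edge_interior)
  dom <- normalise_domain(domain)
  bb <- dom$bbox
  h_int <- max_edge_interior / sqrt(2)
  h_ext <- max_edge_exterior / sqrt(2)
  xs <- axis_breaks(bb[1], bb[2], h_int, extension_width, h_ext)
  ys <- axis_breaks(bb[3], bb[4], h_int, extension_width, h_ext)
  nx <- length(xs); ny <- length(ys)
  verts <- cbind(x = rep(xs, ny), y = rep(ys, each = nx))
  vid <- function(ix, iy) (iy - 1L) * nx + ix
  tri <- vector("list", (nx - 1) * (ny - 1))
  k <- 0L
  for (iy in seq_len(ny - 1)) {
    for (ix in seq_len(nx - 1)) {
      v00 <- vid(ix, iy); v10 <- vid(ix + 1L, iy)
      v01 <- vid(ix, iy + 1L); v11 <- vid(ix + 1L, iy + 1L)
      k <- k + 1L
      tri[[k]] <- rbind(c(v00, v10, v11), c(v00, v11, v01))
    }
  }
  triangles <- do.call(rbind, tri)
  storage.mode(triangles) <- "integer"
  interior <- point_in_polygon(verts, dom$polygon)
  structure(list(vertices = verts, triangles = triangles,
                 interior_mask = interior, xs = xs, ys = ys,
                 domain = dom$polygon,
                 max_edge_interior = max_edge_interior,
                 extension_width = extension_width,
                 max_edge_exterior = max_edge_exterior),
            class = "spde_mesh")
}

#' @export
print.spde_mesh <- function(x, ...) {
  cat("SPDE mesh:", nrow(x$vertices), "vertices,", nrow(x$triangles),
      "triangles (", sum(x$interior_mask), "interior vertices )\n")
  invisible(x)
}

#' Unique edges of a mesh with lengths and interior classification
#'
#' An edge is classified interior when both endpoints lie inside the original
#' domain. Used by the edge-length audit of the mesh constraint.
#'
#' @param mesh an `spde_mesh`.
#' @return data frame `v1`, `v2`, `length`, `interior`.
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  p1 <- mesh$vertices[e[, 1], , drop = FALSE]
  p2 <- mesh$vertices[e[, 2], , drop = FALSE]
  len <- sqrt(rowSums((p1 - p2)^2))
  data.frame(v1 = e[, 1], v2 = e[, 2], length = len,
             interior = mesh$interior_mask[e[, 1]] &
                        mesh$interior_mask[e[, 2]])
}

#' Barycentric projector from mesh vertices to point locations
#'
#' Builds the sparse observation matrix `A` whose row `p` holds the
#' barycentric weights of point `p` within its containing triangle (at most 3
#' nonzeros summing to 1), so that `A %*% field_at_vertices` evaluates the
#' piecewise-linear field at the points. Cell location uses the tensor-grid
#' breakpoints; a point exactly on a cell boundary is assigned to the
#' right/upper cell, and a point on the cell diagonal to the lower triangle
#' (deterministic tie-breaks). Points outside the mesh (including the
#' extension) get an empty row and are flagged, or raise an error in strict
#' mode.
#'
#' @param mesh an `spde_mesh`.
#' @param points matrix or data frame of point coordinates.
#' @param strict error on points outside the mesh (default FALSE).
#' @return list with sparse `A` (n_points x n_vertices) and logical `outside`.
#' @export
make_projector <- function(mesh, points, strict = FALSE) {
  pts <- as.matrix(points)
  if (is.data.frame(points) && all(c("x_km", "y_km") %in% names(points))) {
    pts <- as.matrix(points[, c("x_km", "y_km")])
  }
  stopifnot(all(is.finite(pts)))
  xs <- mesh$xs; ys <- mesh$ys
  nx <- length(xs)
  np <- nrow(pts)
  outside <- pts[, 1] < xs[1] | pts[, 1] > xs[nx] |
             pts[, 2] < ys[1] | pts[, 2] > ys[length(ys)]
  if (strict && any(outside)) {
    stop("points outside mesh: ", paste(head(which(outside), 5), collapse = ", "))
  }
  ii <- jj <- xxw <- list()
  for (p in seq_len(np)) {
    if (outside[p]) next
    ix <- min(max(findInterval(pts[p, 1], xs), 1L), nx - 1L)
    iy <- min(max(findInterval(pts[p, 2], ys), 1L), length(ys) - 1L)
    xi <- (pts[p, 1] - xs[ix]) / (xs[ix + 1] - xs[ix])
    et <- (pts[p, 2] - ys[iy]) / (ys[iy + 1] - ys[iy])
    v00 <- (iy - 1L) * nx + ix
    v10 <- v00 + 1L
    v01 <- v00 + nx
    v11 <- v01 + 1L
    if (xi >= et) {   # lower triangle (v00, v10, v11)
      vs <- c(v00, v10, v11); ws <- c(1 - xi, xi - et, et)
    } else {          # upper triangle (v00, v11, v01)
      vs <- c(v00, v11, v01); ws <- c(1 - et, xi, et - xi)
    }
    keep <- ws > 1e-14
    ii[[p]] <- rep(p, sum(keep)); jj[[p]] <- vs[keep]; xxw[[p]] <- ws[keep]
  }
  A <- Matrix::sparseMatrix(i = as.integer(unlist(ii)),
                            j = as.integer(unlist(jj)),
                            x = as.numeric(unlist(xxw)),
                            dims = c(np, nrow(mesh$vertices)))
  list(A = A, outside = outside)
}
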