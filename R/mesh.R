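## Mesh construction and P1 finite-element matrices for the SPDE field.
##
## Coordinates are treated as planar (longitude/latitude degrees used as
## Euclidean); at the sub-continental scales the package targets this is the
## usual model-based-geostatistics simplification and is documented in the
## vignette.

## -- Bowyer-Watson incremental Delaunay triangulation ------------------------
## Plain R implementation: the environment provides no triangulation library.
## O(n * n_triangles) with vectorised circumcircle tests; adequate for the
## mesh sizes used here (hundreds to a few thousand nodes).
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points to triangulate", call. = FALSE)
  rng <- apply(pts, 2, range)
  scale <- max(rng[2, ] - rng[1, ], 1e-12)
  ctr <- colMeans(rng)
  p <- sweep(sweep(pts, 2, ctr), 2, c(scale, scale), `/`)  # roughly unit box

  # super-triangle far outside the data
  sv <- rbind(c(-30, -20), c(30, -20), c(0, 40))
  P <- rbind(p, sv)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  tri <- matrix(c(s1, s2, s3), ncol = 3)
  circ <- matrix(0, 1, 3)  # cx, cy, r2
  circ[1, ] <- circumcircle(P[s1, ], P[s2, ], P[s3, ])

  for (ip in seq_len(n)) {
    px <- P[ip, 1]; py <- P[ip, 2]
    d2 <- (px - circ[, 1])^2 + (py - circ[, 2])^2
    bad <- which(d2 < circ[, 3] * (1 + 1e-12))
    if (length(bad) == 0L)
      stop("triangulation failed: point outside all circumcircles ",
           "(degenerate input?)", call. = FALSE)
    # cavity boundary = edges of bad triangles that appear exactly once
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    keep <- !(ekey %in% ekey[duplicated(ekey)])
    e <- e[keep, , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    circ <- circ[-bad, , drop = FALSE]
    newt <- cbind(e, ip)
    newc <- t(vapply(seq_len(nrow(newt)), function(k)
      circumcircle(P[newt[k, 1], ], P[newt[k, 2], ], P[newt[k, 3], ]),
      numeric(3)))
    tri <- rbind(tri, newt)
    circ <- rbind(circ, newc)
  }
  # drop triangles meeting the super vertices
  keep <- rowSums(matrix(tri %in% c(s1, s2, s3), nrow(tri))) == 0L
  tri <- tri[keep, , drop = FALSE]
  if (nrow(tri) == 0L)
    stop("degenerate (collinear?) input: no triangles produced", call. = FALSE)
  orient_ccw(tri, pts)
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-300) return(c(0, 0, Inf))  # collinear: swallow everything
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

orient_ccw <- function(tri, nodes) {
  a <- signed_areas(tri, nodes)
  flip <- a < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  tri
}

signed_areas <- function(tri, nodes) {
  x <- matrix(nodes[tri, 1], ncol = 3); y <- matrix(nodes[tri, 2], ncol = 3)
  0.5 * ((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
         (x[, 3] - x[, 1]) * (y[, 2] - y[, 1]))
}

## -- Mesh constructors -------------------------------------------------------

#' Build a triangulated mesh from point locations
#'
#' Delaunay-triangulates the input points, augmented with a ring of boundary
#' nodes extending the data's convex hull by `buffer_fraction` of the domain
#' diameter (mitigating SPDE boundary effects) and, if `max_edge` is given,
#' with a filler lattice at that spacing so triangle edges stay below roughly
#' `max_edge` even where data are sparse. All input points are mesh nodes
#' (the first `nrow(points)` nodes, in order).
#'
#' @param points Numeric `n x 2` matrix of (lon, lat) locations, `n >= 3`,
#'   not all collinear.
#' @param buffer_fraction Width of the boundary extension as a fraction of the
#'   domain diameter (default 0.25). Zero disables the buffer ring.
#' @param max_edge Target maximum edge length for filler nodes; `NULL`
#'   (default) adds no filler lattice.
#' @return An object of class `spatord_mesh`: list with `nodes` (m x 2),
#'   `triangles` (t x 3 indices, counter-clockwise), lumped mass matrix `C`
#'   (diagonal, as vector `c_diag`), stiffness matrix `G` (sparse symmetric)
#'   and `n_input` (number of leading nodes that are input points).
#' @export
build_mesh <- function(points, buffer_fraction = 0.25, max_edge = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L || nrow(points) < 3L)
    stop("points must be an n x 2 matrix with n >= 3", call. = FALSE)
  if (any(!is.finite(points))) stop("non-finite coordinates", call. = FALSE)
  uq <- !duplicated(points)
  base <- points[uq, , drop = FALSE]
  if (nrow(base) < 3L) stop("fewer than 3 distinct points", call. = FALSE)

  rng <- apply(base, 2, range)
  diam <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  if (diam <= 0) stop("degenerate point cloud", call. = FALSE)
  ctr <- colMeans(rng)
  extra <- NULL
  if (buffer_fraction > 0) {
    R <- diam / 2 + buffer_fraction * diam
    n_ring <- if (is.null(max_edge)) 16L else
      max(8L, ceiling(2 * pi * R / max_edge))
    ang <- seq(0, 2 * pi, length.out = n_ring + 1L)[-1L]
    extra <- cbind(ctr[1] + R * cos(ang), ctr[2] + R * sin(ang))
  }
  if (!is.null(max_edge)) {
    stopifnot(max_edge > 0)
    pad <- if (buffer_fraction > 0) buffer_fraction * diam else 0
    gx <- seq(rng[1, 1] - pad, rng[2, 1] + pad, by = max_edge)
    gy <- seq(rng[1, 2] - pad, rng[2, 2] + pad, by = max_edge)
    lat <- as.matrix(expand.grid(gx, gy))
    # deterministic micro-jitter so lattice points are never exactly cocircular
    k <- seq_len(nrow(lat))
    lat <- lat + 1e-5 * max_edge *
      cbind(((k * 2654435761) %% 1009) / 1009 - 0.5,
            ((k * 40503) %% 997) / 997 - 0.5)
    if (buffer_fraction > 0) {
      R <- diam / 2 + buffer_fraction * diam
      lat <- lat[(lat[, 1] - ctr[1])^2 + (lat[, 2] - ctr[2])^2 < R^2, ,
                 drop = FALSE]
    }
    # keep filler away from data nodes
    if (nrow(lat)) {
      dmin <- fast_min_dist(lat, base)
      lat <- lat[dmin > 0.45 * max_edge, , drop = FALSE]
      extra <- rbind(extra, lat)
    }
  }
  nodes <- rbind(base, extra)
  tri <- delaunay_triangulate(nodes)
  mesh <- fem_mesh(nodes, tri, n_input = nrow(base))
  mesh$input_index <- match(
    paste(points[, 1], points[, 2]), paste(base[, 1], base[, 2]))
  mesh
}

fast_min_dist <- function(a, b) {
  # min distance from each row of a to rows of b, chunked to bound memory
  out <- numeric(nrow(a))
  idx <- split(seq_len(nrow(a)), ceiling(seq_len(nrow(a)) / 512))
  for (ii in idx) {
    d2 <- outer(a[ii, 1], b[, 1], `-`)^2 + outer(a[ii, 2], b[, 2], `-`)^2
    out[ii] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Build a structured lattice mesh over a rectangle
#'
#' Regular grid of nodes with each cell split into two triangles (diagonal
#' direction alternating by cell parity). Used for fine-resolution checks of
#' the SPDE approximation where an exactly regular mesh is wanted.
#'
#' @param xlim,ylim Numeric length-2 ranges.
#' @param spacing Node spacing (same units as the coordinates).
#' @return An object of class `spatord_mesh` (see [build_mesh()]).
#' @export
build_mesh_grid <- function(xlim, ylim, spacing) {
  stopifnot(spacing > 0, diff(xlim) > 0, diff(ylim) > 0)
  gx <- seq(xlim[1], xlim[2], by = spacing)
  gy <- seq(ylim[1], ylim[2], by = spacing)
  nx <- length(gx); ny <- length(gy)
  nodes <- cbind(rep(gx, times = ny), rep(gy, each = nx))
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- id(i, j); b <- id(i + 1L, j); cc <- id(i + 1L, j + 1L); d <- id(i, j + 1L)
  alt <- (i + j) %% 2L == 0L
  # alternate the cell diagonal by parity to avoid a directional bias
  tri <- rbind(
    cbind(a, b, ifelse(alt, cc, d)),
    cbind(ifelse(alt, a, b), cc, d))
  fem_mesh(nodes, orient_ccw(tri, nodes), n_input = nrow(nodes))
}

fem_mesh <- function(nodes, triangles, n_input) {
  fm <- fem_matrices(nodes, triangles)
  structure(list(nodes = nodes, triangles = triangles,
                 c_diag = fm$c_diag, C = fm$C, G = fm$G,
                 G2 = fm$G2, n_input = n_input),
            class = "spatord_mesh")
}

#' @export
print.spatord_mesh <- function(x, ...) {
  cat("spatord mesh:", nrow(x$nodes), "nodes,", nrow(x$triangles),
      "triangles, area", format(sum(x$c_diag), digits = 6), "\n")
  invisible(x)
}

#' P1 finite-element mass and stiffness matrices
#'
#' Assembles the lumped (diagonal) mass matrix `C` with
#' `C_ii = (1/3) * sum(area of triangles incident to node i)` and the standard
#' piecewise-linear stiffness matrix `G` (`G %*% 1 = 0`). Also returns
#' `G2 = G C^-1 G`, the third term of the SPDE precision, which is sparse
#' because `C` is lumped.
#'
#' @param nodes `m x 2` node coordinates.
#' @param triangles `t x 3` node indices.
#' @return List with `c_diag` (vector of `C` diagonal), `C` (sparse diagonal),
#'   `G`, `G2` (sparse symmetric).
#' @export
fem_matrices <- function(nodes, triangles) {
  nodes <- as.matrix(nodes); triangles <- as.matrix(triangles)
  m <- nrow(nodes)
  if (any(triangles < 1L | triangles > m)) stop("triangle index out of range")
  area <- signed_areas(triangles, nodes)
  if (any(area < 0)) {
    triangles <- orient_ccw(triangles, nodes)
    area <- abs(area)
  }
  bad <- which(area <= 1e-14)
  if (length(bad))
    stop("zero-area triangle(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  x <- matrix(nodes[triangles, 1], ncol = 3)
  y <- matrix(nodes[triangles, 2], ncol = 3)
  # gradient coefficients of the three hat functions on each triangle
  b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
  cc <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1
    ii[[k]] <- triangles[, i]; jj[[k]] <- triangles[, j]
    xx[[k]] <- (b[, i] * b[, j] + cc[, i] * cc[, j]) / (4 * area)
  }
  G <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(m, m))
  G <- Matrix::forceSymmetric((G + Matrix::t(G)) / 2)
  c_diag <- numeric(m)
  tab <- rowsum(rep(area / 3, 3), as.vector(triangles))
  c_diag[as.integer(rownames(tab))] <- tab[, 1]
  if (any(c_diag <= 0))
    stop("mesh has nodes not touched by any triangle", call. = FALSE)
  C <- Matrix::Diagonal(m, c_diag)
  G2 <- Matrix::forceSymmetric(G %*% Matrix::Diagonal(m, 1 / c_diag) %*% G)
  list(c_diag = c_diag, C = C, G = G, G2 = G2)
}

#' Barycentric projection matrix from mesh nodes to point locations
#'
#' Row `i` holds the barycentric weights of location `i` within its containing
#' triangle (at most 3 nonzeros, nonnegative, summing to 1), so `A %*% w`
#' linearly interpolates mesh-node field values to the locations. Locations
#' outside the mesh get an all-zero row; their indices are attached as
#' attribute `"outside"` and reported via a warning.
#'
#' @param mesh A `spatord_mesh`.
#' @param locations `q x 2` matrix of (lon, lat) points.
#' @return Sparse `q x m` matrix with attribute `outside` (integer indices).
#' @export
projection_matrix <- function(mesh, locations) {
  locations <- as.matrix(locations)
  stopifnot(inherits(mesh, "spatord_mesh"), ncol(locations) == 2L)
  tri <- mesh$triangles; nodes <- mesh$nodes
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  q <- nrow(locations)
  ri <- rj <- rx <- vector("list", q)
  outside <- integer(0)
  tol <- -1e-9
  for (k in seq_len(q)) {
    px <- locations[k, 1]; py <- locations[k, 2]
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
    l3 <- 1 - l1 - l2
    hit <- which(l1 >= tol & l2 >= tol & l3 >= tol)
    if (length(hit) == 0L) {
      outside <- c(outside, k)
      next
    }
    h <- hit[1L]
    w <- pmax(c(l1[h], l2[h], l3[h]), 0)
    w <- w / sum(w)
    ri[[k]] <- rep.int(k, 3L); rj[[k]] <- tri[h, ]; rx[[k]] <- w
  }
  ii <- unlist(ri); jj <- unlist(rj); xx <- unlist(rx)
  if (is.null(ii)) { ii <- integer(0); jj <- integer(0); xx <- numeric(0) }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(q, nrow(nodes)))
  if (length(outside))
    warning(length(outside), " location(s) outside the mesh; ",
            "their projection rows are zero", call. = FALSE)
  attr(A, "outside") <- outside
  A
}
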