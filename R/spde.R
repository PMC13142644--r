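## SPDE representation of the Matern (nu = 1) Gaussian random field.
##
## The field u(s) solves (kappa^2 - Laplacian) u = tau^-1 W on the mesh, i.e.
## alpha = 2, giving Matern smoothness nu = alpha - d/2 = 1 in d = 2. On the
## P1 finite-element basis the precision of the node weights is the sparse
## three-term matrix
##   Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G),
## and tau is chosen so the field's marginal variance is sigma_u^2.

#' Convert between practical range and the SPDE scale parameter
#'
#' The practical range is the distance at which the Matern (nu = 1)
#' correlation falls to about 0.14 — the conventional "distance beyond which
#' spatial correlation becomes negligible": `kappa = sqrt(8 * nu) / range`
#' with `nu = 1`.
#'
#' @param range Practical range in coordinate units, `> 0`.
#' @return `kappa`, the inverse-scale parameter.
#' @examples
#' range_to_kappa(sqrt(8))  # 1
#' @export
range_to_kappa <- function(range) {
  if (!is.numeric(range) || any(range <= 0) || any(!is.finite(range)))
    stop("range must be positive and finite", call. = FALSE)
  sqrt(8) / range
}

#' @rdname range_to_kappa
#' @param kappa Inverse-scale parameter, `> 0`.
#' @export
kappa_to_range <- function(kappa) {
  if (!is.numeric(kappa) || any(kappa <= 0) || any(!is.finite(kappa)))
    stop("kappa must be positive and finite", call. = FALSE)
  sqrt(8) / kappa
}

#' Matern correlation with smoothness nu = 1
#'
#' `rho(h) = kappa * h * K_1(kappa * h)`, where `K_1` is the modified Bessel
#' function of the second kind; `rho(0) = 1`. At `h = range` the value is
#' `sqrt(8) * K_1(sqrt(8))` which is approximately 0.1397.
#'
#' @param h Nonnegative distances.
#' @param range Practical range (`kappa = sqrt(8) / range`).
#' @return Correlations in `[0, 1]`.
#' @export
matern_correlation <- function(h, range) {
  kh <- range_to_kappa(range) * h
  out <- ifelse(kh == 0, 1, kh * besselK(pmax(kh, 1e-300), 1))
  out[kh > 700] <- 0
  out
}

#' Sparse SPDE precision matrix of the Matern field's node weights
#'
#' @param mesh A `spatord_mesh` from [build_mesh()] or [build_mesh_grid()].
#' @param range Practical range, `> 0` (coordinate units).
#' @param sigma_u Marginal standard deviation of the field, `> 0`.
#' @return Sparse symmetric positive-definite matrix `Q` (class from the
#'   Matrix package) of dimension `n_nodes x n_nodes`.
#' @export
precision_matrix <- function(mesh, range, sigma_u) {
  stopifnot(inherits(mesh, "spatord_mesh"))
  if (!is.finite(sigma_u) || sigma_u <= 0)
    stop("sigma_u must be > 0 (drop the spatial field instead of setting it to 0)",
         call. = FALSE)
  kappa <- range_to_kappa(range)
  tau <- 1 / (sqrt(4 * pi) * kappa * sigma_u)  # marginal variance sigma_u^2
  Q <- tau^2 * (kappa^4 * mesh$C + 2 * kappa^2 * mesh$G + mesh$G2)
  Matrix::forceSymmetric(Q)
}

#' Sample a Matern (nu = 1) Gaussian random field at point locations
#'
#' Draws one zero-mean realisation with covariance
#' `sigma_u^2 * (kappa h) K_1(kappa h)`. For `n <= dense_cap` locations the
#' draw uses the exact dense covariance and its Cholesky factor; above the
#' cap it samples SPDE node weights from the sparse precision on a fine
#' lattice mesh and interpolates, trading exactness for scalability.
#' Duplicate locations make the dense covariance singular; a `1e-8` diagonal
#' jitter is added with a warning (households share cluster coordinates by
#' design, so duplicates are expected).
#'
#' @param locations `n x 2` coordinate matrix.
#' @param spatial_range Practical range, `> 0`.
#' @param sigma_u Marginal SD, `>= 0` (0 returns the zero vector).
#' @param seed Integer seed; the draw is deterministic given it.
#' @param dense_cap Largest `n` for the dense-Cholesky path (default 2000).
#' @return Numeric vector of field values, one per location.
#' @export
sample_grf <- function(locations, spatial_range, sigma_u, seed = NULL,
                       dense_cap = 2000) {
  locations <- as.matrix(locations)
  n <- nrow(locations)
  stopifnot(n >= 1L, ncol(locations) == 2L)
  if (!is.finite(sigma_u) || sigma_u < 0)
    stop("sigma_u must be nonnegative", call. = FALSE)
  if (sigma_u == 0) return(numeric(n))
  if (spatial_range <= 0) stop("spatial_range must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n <= dense_cap) {
    h <- as.matrix(stats::dist(locations))
    S <- sigma_u^2 * matern_correlation(h, spatial_range)
    if (any(h[upper.tri(h)] < 1e-12)) {
      warning("duplicate (or near-duplicate) locations: adding 1e-8 jitter ",
              "to the covariance diagonal", call. = FALSE)
      diag(S) <- diag(S) + 1e-8
    }
    L <- tryCatch(chol(S), error = function(e) {
      diag(S) <- diag(S) + 1e-8
      chol(S)
    })
    drop(crossprod(L, stats::rnorm(n)))
  } else {
    rng <- apply(locations, 2, range)
    pad <- 0.5 * spatial_range
    mesh <- build_mesh_grid(c(rng[1, 1] - pad, rng[2, 1] + pad),
                            c(rng[1, 2] - pad, rng[2, 2] + pad),
                            spacing = spatial_range / 4)
    w <- sample_spde(mesh, spatial_range, sigma_u, n_samples = 1)
    as.numeric(projection_matrix(mesh, locations) %*% w)
  }
}

#' Sample SPDE node weights from the sparse precision
#'
#' Draws `w ~ N(0, Q^-1)` via the permuted sparse Cholesky factorisation of
#' `Q`. Used for field simulation on meshes and for checking the SPDE
#' approximation against the closed-form Matern covariance.
#'
#' @inheritParams precision_matrix
#' @param n_samples Number of independent draws.
#' @param seed Optional integer seed.
#' @return `n_nodes x n_samples` matrix of node weights.
#' @export
sample_spde <- function(mesh, range, sigma_u, n_samples = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  Q <- precision_matrix(mesh, range, sigma_u)
  ch <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
  m <- nrow(Q)
  z <- matrix(stats::rnorm(m * n_samples), m, n_samples)
  # Q = P' L L' P  =>  w = P' solve(L', z) has covariance Q^-1
  y <- Matrix::solve(ch, z, system = "Lt")
  as.matrix(Matrix::solve(ch, y, system = "Pt"))
}
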