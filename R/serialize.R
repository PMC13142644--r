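## Plain-text serialization of fitted models and meshes: a YAML metadata
## file plus CSV arrays in a directory container. Everything needed for
## prediction (parameters, covariance, random-effect modes, conditional
## Hessian, mesh, standardization) round-trips; the training design matrix
## and outcomes are not stored, so training-data methods (fitted,
## residuals, simulate) require the original dataset.

#' Write / read a mesh as plain-text CSV tables
#'
#' Nodes and triangles are stored as `<path>_nodes.csv` and
#' `<path>_triangles.csv`; the finite-element matrices are recomputed on
#' read (they are functions of the geometry).
#'
#' @param mesh A `spatord_mesh`.
#' @param path Base path without extension.
#' @return `write_mesh` the paths, invisibly; `read_mesh` the mesh.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "spatord_mesh"))
  pn <- paste0(path, "_nodes.csv"); pt <- paste0(path, "_triangles.csv")
  utils::write.csv(data.frame(lon = mesh$nodes[, 1], lat = mesh$nodes[, 2],
                              input = seq_len(nrow(mesh$nodes)) <= mesh$n_input),
                   pn, row.names = FALSE)
  utils::write.csv(as.data.frame(mesh$triangles), pt, row.names = FALSE)
  invisible(c(pn, pt))
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  nd <- utils::read.csv(paste0(path, "_nodes.csv"))
  tr <- as.matrix(utils::read.csv(paste0(path, "_triangles.csv")))
  dimnames(tr) <- NULL
  fem_mesh(cbind(nd$lon, nd$lat), tr, n_input = sum(nd$input))
}

#' Serialize a fitted model to a plain-text directory container
#'
#' Writes `model.yaml` (parameters, convergence, dimensions,
#' standardization) plus CSV arrays: outer parameter covariance,
#' random-effect modes, the sparse conditional Hessian in triplet form,
#' cluster coordinates and the mesh. The container is diffable text; no
#' binary formats.
#'
#' @param model A fitted `spatord` model.
#' @param dir Directory to create.
#' @param overwrite Replace an existing container.
#' @return The directory, invisibly.
#' @export
write_model <- function(model, dir, overwrite = FALSE) {
  stopifnot(inherits(model, "spatord"))
  if (dir.exists(dir)) {
    if (!overwrite) stop("directory exists (use overwrite = TRUE): ", dir,
                         call. = FALSE)
    unlink(dir, recursive = TRUE)
  }
  dir.create(dir, recursive = TRUE)
  meta <- list(
    package = "spatord", container_version = 1L,
    K = model$K, design = as.list(model$design),
    cluster_re = model$cluster_re, spatial = model$spatial,
    par = as.list(model$par),
    convergence = model$convergence[c("converged", "outer_iterations",
                                      "gradient_norm", "marginal_nll")],
    standardization = if (!is.null(model$standardization))
      lapply(seq_len(nrow(model$standardization)), function(i)
        as.list(model$standardization[i, ]))
  )
  yaml::write_yaml(meta, file.path(dir, "model.yaml"), precision = 15)
  utils::write.csv(as.data.frame(model$param_cov),
                   file.path(dir, "param_cov.csv"), row.names = FALSE)
  if (model$cluster_re)
    utils::write.csv(data.frame(b = model$re_mode$b),
                     file.path(dir, "mode_b.csv"), row.names = FALSE)
  if (model$spatial) {
    utils::write.csv(data.frame(w = model$re_mode$w),
                     file.path(dir, "mode_w.csv"), row.names = FALSE)
    write_mesh(model$mesh, file.path(dir, "mesh"))
  }
  if (!is.null(model$conditional_hessian)) {
    Ht <- as(model$conditional_hessian, "TsparseMatrix")
    utils::write.csv(data.frame(i = Ht@i + 1L, j = Ht@j + 1L, x = Ht@x),
                     file.path(dir, "hessian.csv"), row.names = FALSE)
  }
  utils::write.csv(data.frame(cluster_id = seq_len(nrow(model$coords)),
                              lon = model$coords[, 1], lat = model$coords[, 2]),
                   file.path(dir, "clusters.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  par <- unlist(meta$par)
  K <- meta$K
  design <- unlist(meta$design)
  p <- length(design)
  up <- unpack_par(par, p, K, meta$cluster_re, meta$spatial)
  up$beta <- stats::setNames(up$beta, design)
  pc <- as.matrix(utils::read.csv(file.path(dir, "param_cov.csv")))
  dimnames(pc) <- list(names(par), names(par))
  clusters <- utils::read.csv(file.path(dir, "clusters.csv"))
  coords <- as.matrix(clusters[, c("lon", "lat")])
  mesh <- NULL; A <- NULL; w <- NULL; b <- NULL; H <- NULL
  if (meta$spatial) {
    mesh <- read_mesh(file.path(dir, "mesh"))
    A <- projection_matrix(mesh, coords)
    w <- utils::read.csv(file.path(dir, "mode_w.csv"))$w
  }
  if (meta$cluster_re) b <- utils::read.csv(file.path(dir, "mode_b.csv"))$b
  hp <- file.path(dir, "hessian.csv")
  if (file.exists(hp)) {
    ht <- utils::read.csv(hp)
    n_re <- length(b) + length(w)
    H <- Matrix::sparseMatrix(i = ht$i, j = ht$j, x = ht$x,
                              dims = c(n_re, n_re), symmetric = FALSE)
    H <- Matrix::forceSymmetric(H)
  }
  std <- if (!is.null(meta$standardization))
    do.call(rbind, lapply(meta$standardization, as.data.frame))
  structure(list(
    call = NULL, formula = NULL,
    params = up, par = par, param_cov = pc,
    re_mode = list(b = b, w = w), conditional_hessian = H,
    mesh = mesh, A = A, X = NULL, y = NULL,
    cluster = seq_len(nrow(clusters)), coords = coords,
    K = K, design = design,
    cluster_re = isTRUE(meta$cluster_re), spatial = isTRUE(meta$spatial),
    standardization = std, config = NULL, control = spatord_control(),
    convergence = meta$convergence),
    class = "spatord")
}
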