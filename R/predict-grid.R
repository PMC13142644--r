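## Gridded prediction surfaces: per-class probability and delta-method
## standard-error layers on a regular lon/lat grid, written as GeoTIFF
## rasters following the [component]_prob_[class].tif naming convention.

#' Evaluate a fitted model on a prediction grid
#'
#' Per grid cell, the latent mean is `z* = x*' beta + a*' w` (covariates from
#' the grid layers, the spatial field interpolated from its conditional mode;
#' the cluster effect is a survey-design artifact and is set to its mean 0).
#' Class probabilities follow the cumulative-logit formula; standard errors
#' come from the delta method on the linear predictor:
#' `Var(z*) = x*' Cov(beta) x* + a*' Cov(w | data) a*` and
#' `SE(p_k) = |dp_k/dz| sd(z*)` at the plug-in estimates (thresholds fixed;
#' the beta-w cross term is omitted). Cells outside the mesh or with
#' non-finite covariates are masked to `NaN`.
#'
#' @param model Fitted `spatord` model.
#' @param grid A `prediction_grid`.
#' @param date Optional prediction date overriding the grid's time layer
#'   (standardized with the training statistics).
#' @param se Compute SE layers (default `TRUE`).
#' @param include_spatial_uncertainty,include_fixed_uncertainty Toggle the
#'   two components of `Var(z*)`.
#' @return Object of class `spatord_surface`: `prob` and `se` (lists of K
#'   matrices in grid orientation `n_lon x n_lat`), `sd_link`, `mask`,
#'   axes and resolution.
#' @export
predict_grid <- function(model, grid, date = NULL, se = TRUE,
                         include_spatial_uncertainty = TRUE,
                         include_fixed_uncertainty = TRUE) {
  stopifnot(inherits(model, "spatord"), inherits(grid, "prediction_grid"))
  nx <- length(grid$lon_axis); ny <- length(grid$lat_axis)
  layers <- grid$layers
  if (!is.null(date)) {
    tn <- intersect(model$design, model$standardization$name)
    if ("time" %in% names(layers)) {
      i <- match("time", model$standardization$name)
      layers$time <- matrix(standardize(time_covariate(date),
                                        model$standardization$mean[i],
                                        model$standardization$sd[i]), nx, ny)
    }
  }
  missing_cov <- setdiff(model$design, names(layers))
  if (length(missing_cov))
    stop("grid is missing covariate layer(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  X <- do.call(cbind, lapply(model$design, function(nm) as.vector(layers[[nm]])))
  colnames(X) <- model$design
  finite_ok <- rowSums(!is.finite(X)) == 0
  lon <- rep(grid$lon_axis, times = ny); lat <- rep(grid$lat_axis, each = nx)

  z <- drop(X %*% model$params$beta)
  A <- NULL
  inside <- rep(TRUE, nx * ny)
  if (model$spatial) {
    A <- suppressWarnings(projection_matrix(model$mesh, cbind(lon, lat)))
    outside <- attr(A, "outside")
    if (length(outside)) inside[outside] <- FALSE
    z <- z + drop(A %*% model$re_mode$w)
  }
  mask <- finite_ok & inside
  probs <- class_probabilities(z, model$params$thresholds)
  probs[!mask, ] <- NaN
  to_mats <- function(M) lapply(seq_len(ncol(M)),
                                function(k) matrix(M[, k], nx, ny))
  out <- list(lon_axis = grid$lon_axis, lat_axis = grid$lat_axis,
              resolution = grid$resolution, K = model$K,
              prob = to_mats(probs), mask = matrix(mask, nx, ny),
              sd_link = NULL, se = NULL,
              uncertainty = c(fixed = include_fixed_uncertainty,
                              spatial = include_spatial_uncertainty))
  if (se) {
    sd_z <- sqrt(latent_variance(model, X, A,
                                 include_fixed_uncertainty,
                                 include_spatial_uncertainty))
    ses <- abs(class_prob_dz(z, model$params$thresholds)) * sd_z
    ses[!mask, ] <- NaN
    out$sd_link <- matrix(ifelse(mask, sd_z, NaN), nx, ny)
    out$se <- to_mats(ses)
  }
  structure(out, class = "spatord_surface")
}

#' @export
print.spatord_surface <- function(x, ...) {
  cat("spatord_surface:", length(x$lon_axis), "x", length(x$lat_axis),
      "cells,", x$K, "classes,", sum(!x$mask), "masked cells\n")
  invisible(x)
}

## grid-orientation matrix (n_lon x n_lat, lat ascending) -> raster rows
## (north to south)
grid_to_raster <- function(layer) t(layer)[rev(seq_len(ncol(layer))), ,
                                           drop = FALSE]

#' Write probability and SE surfaces as GeoTIFF rasters
#'
#' One float32 GeoTIFF per class, named `{component}_prob_{class}.tif` and
#' `{component}_se_{class}.tif` (e.g. `water_prob_ImpW_Pipe.tif`), EPSG:4326,
#' NaN nodata, cell-registered at the grid resolution.
#'
#' @param surface A `spatord_surface` from [predict_grid()].
#' @param component Component name (e.g. `"water"`, `"sanitation"`,
#'   `"hygiene"`).
#' @param class_names Character vector of K class codes, ordered from the
#'   reference category upward (e.g. `"UnimpW_Srf"`, ..., `"ImpW_Pipe"`).
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow overwriting existing files (default `FALSE`:
#'   existing files are an error).
#' @return Character vector of file paths written.
#' @export
write_rasters <- function(surface, component, class_names, out_dir,
                          overwrite = FALSE) {
  stopifnot(inherits(surface, "spatord_surface"))
  if (length(class_names) != surface$K)
    stop("class_names must have length K = ", surface$K, call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- surface$resolution
  origin <- c(min(surface$lon_axis) - res / 2, max(surface$lat_axis) + res / 2)
  paths <- character(0)
  emit <- function(layer, kind, cls) {
    f <- file.path(out_dir, sprintf("%s_%s_%s.tif", component, kind, cls))
    if (file.exists(f) && !overwrite)
      stop("file exists (use overwrite = TRUE): ", f, call. = FALSE)
    write_geotiff(grid_to_raster(layer), f, origin, c(res, res))
    f
  }
  for (k in seq_len(surface$K)) {
    paths <- c(paths, emit(surface$prob[[k]], "prob", class_names[k]))
    if (!is.null(surface$se))
      paths <- c(paths, emit(surface$se[[k]], "se", class_names[k]))
  }
  paths
}
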