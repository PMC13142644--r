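## Synthetic cluster-sampled household surveys with the exact generative
## structure assumed by the model: clusters scattered uniformly over a
## bounding box, 25-30 households per cluster, standardized continuous
## covariates (smooth spatial trend + local noise), optional categorical
## factors, a log-time covariate, an i.i.d. Gaussian cluster effect, a Matern
## spatial field shared by all households of a cluster, and ordinal outcomes
## from the cumulative-logit latent model.

#' Configuration for the synthetic survey generator
#'
#' Defaults describe a DHS/MICS-style survey over a 4 x 4 degree domain:
#' 150 clusters of 25-30 households, a 4-category outcome driven by two
#' smooth continuous covariates and a log-time covariate, cluster SD 0.5,
#' spatial practical range 1.5 degrees and spatial SD 0.75.
#'
#' @param n_clusters Number of survey clusters (primary sampling units).
#' @param households_per_cluster Integer range `c(low, high)`; per-cluster
#'   counts are uniform on it. Bounds must lie in `[1, 1000]`.
#' @param K Number of ordinal outcome categories, 2 to 5 (category 0 is the
#'   least-improved reference level).
#' @param beta Fixed-effect coefficients, one per design column implied by
#'   `covariate_spec` (categorical factors contribute `levels - 1` columns).
#' @param thresholds Strictly increasing vector of `K - 1` latent thresholds.
#' @param sigma_b Cluster random-effect SD, `>= 0`.
#' @param spatial_range Practical range of the Matern field, `> 0`
#'   (coordinate units, i.e. degrees).
#' @param sigma_u Marginal SD of the Matern field, `>= 0`.
#' @param domain Bounding box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param covariate_spec List of covariate descriptors, each a list with
#'   `name`, `kind` (`"continuous"`, `"categorical"` or `"time"`) and
#'   kind-specific parameters: continuous takes `trend_sd` and `noise_sd`;
#'   categorical takes `levels` and `probs`; time takes `date_range`
#'   (two `Date`s, both after 2005-01-01).
#' @param seed Integer seed making the whole draw reproducible.
#' @return An object of class `survey_config`.
#' @export
survey_config <- function(n_clusters = 150,
                          households_per_cluster = c(25, 30),
                          K = 4,
                          beta = c(0.8, -0.5, 0.3),
                          thresholds = c(-1, 0.5, 2),
                          sigma_b = 0.5,
                          spatial_range = 1.5,
                          sigma_u = 0.75,
                          domain = c(30, 34, -4, 0),
                          covariate_spec = default_covariate_spec(),
                          seed = 1L) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              households_per_cluster = as.integer(households_per_cluster),
              K = as.integer(K), beta = as.numeric(beta),
              thresholds = as.numeric(thresholds),
              sigma_b = sigma_b, spatial_range = spatial_range,
              sigma_u = sigma_u, domain = as.numeric(domain),
              covariate_spec = covariate_spec, seed = as.integer(seed))
  validate_survey_config(cfg)
  structure(cfg, class = "survey_config")
}

#' @rdname survey_config
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "hdi",   kind = "continuous", trend_sd = 1, noise_sd = 0.3),
    list(name = "night", kind = "continuous", trend_sd = 1, noise_sd = 0.3),
    list(name = "time",  kind = "time",
         date_range = as.Date(c("2006-01-01", "2024-01-01"))))
}

validate_survey_config <- function(cfg) {
  with(cfg, {
    if (n_clusters < 1L) stop("n_clusters must be positive", call. = FALSE)
    if (K < 2L || K > 5L)
      stop("K must be between 2 and 5 (at most five outcome categories)",
           call. = FALSE)
    if (length(thresholds) != K - 1L)
      stop("thresholds must have length K - 1", call. = FALSE)
    check_thresholds(thresholds)
    h <- households_per_cluster
    if (length(h) != 2L || h[1] > h[2] || h[1] < 1L || h[2] > 1000L)
      stop("households_per_cluster must be c(low, high) within [1, 1000]",
           call. = FALSE)
    if (sigma_b < 0 || sigma_u < 0) stop("SDs must be nonnegative", call. = FALSE)
    if (spatial_range <= 0) stop("spatial_range must be > 0", call. = FALSE)
    if (length(domain) != 4L || domain[1] >= domain[2] || domain[3] >= domain[4])
      stop("domain must be c(lon_min, lon_max, lat_min, lat_max)", call. = FALSE)
    p <- sum(vapply(covariate_spec, function(cv)
      if (cv$kind == "categorical") length(cv$levels) - 1L else 1L, integer(1)))
    if (p != length(beta))
      stop("beta has length ", length(beta), " but covariate_spec implies ",
           p, " design columns", call. = FALSE)
  })
  invisible(cfg)
}

#' Log-time covariate
#'
#' Natural log of the number of whole days elapsed since 2005-01-01, the
#' temporal covariate entering the fixed effects.
#'
#' @param date A `Date` (or string coercible to one), strictly after
#'   2005-01-01.
#' @return `log(days since 2005-01-01)`.
#' @examples
#' time_covariate("2005-01-02")  # 0
#' time_covariate("2024-01-01")  # log(6939) = 8.8449
#' @export
time_covariate <- function(date) {
  date <- as.Date(date)
  days <- as.numeric(date - as.Date("2005-01-01"))
  if (any(days <= 0))
    stop("date must be strictly after 2005-01-01", call. = FALSE)
  log(days)
}

## Smooth continuous covariate surface: quadratic trend with random
## coefficients over domain-scaled coordinates. Keeping the surface low-order
## makes covariates and the Matern field distinguishable in recovery tests.
draw_surface <- function(trend_sd) {
  list(coef = stats::rnorm(5, 0, trend_sd))
}

eval_surface <- function(surface, lon, lat, domain) {
  t1 <- 2 * (lon - domain[1]) / (domain[2] - domain[1]) - 1
  t2 <- 2 * (lat - domain[3]) / (domain[4] - domain[3]) - 1
  B <- cbind(t1, t2, t1 * t2, t1^2 - 1 / 3, t2^2 - 1 / 3)
  drop(B %*% surface$coef)
}

#' Standardize / destandardize with stored statistics
#'
#' @param x Numeric vector.
#' @param center,scale Training mean and SD.
#' @return `(x - center) / scale` (or its inverse).
#' @export
standardize <- function(x, center, scale) (x - center) / scale

#' @rdname standardize
#' @export
destandardize <- function(x, center, scale) x * scale + center

#' Simulate a cluster-sampled ordinal household survey
#'
#' Generates a complete synthetic survey from a [survey_config()]: cluster
#' locations uniform over the domain, household counts uniform over the
#' configured range, covariates drawn per the covariate spec (continuous ones
#' standardized to the training mean/SD, categoricals one-hot encoded against
#' the first level), cluster effects `b ~ N(0, sigma_b^2)`, a Matern field
#' `u` sampled at cluster locations (all households of a cluster share its
#' coordinates and field value), latent means `z = X beta + u + b` and
#' categories drawn from the cumulative-logit probabilities. All randomness
#' flows through one seeded stream in a fixed order (locations, counts,
#' covariates in spec order, cluster effects, field, outcomes), so the same
#' config reproduces the identical dataset.
#'
#' @param config A `survey_config`.
#' @return Object of class `survey_dataset`: list with `households`
#'   (data.frame: household_id, cluster_id, lon, lat, design columns, y),
#'   `clusters`, `design` (design column names, ordered as `beta`),
#'   `K`, `standardization` (name/mean/sd per standardized column), `truth`
#'   (b, u, z, probabilities per household) and the `config`.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  validate_survey_config(config)
  set.seed(config$seed)
  nc <- config$n_clusters
  dom <- config$domain

  cl_lon <- stats::runif(nc, dom[1], dom[2])
  cl_lat <- stats::runif(nc, dom[3], dom[4])
  h <- config$households_per_cluster
  n_hh <- if (h[1] == h[2]) rep(h[1], nc) else
    sample(seq(h[1], h[2]), nc, replace = TRUE)
  n <- sum(n_hh)
  cl_of <- rep(seq_len(nc), n_hh)

  # covariates (cluster-level, as survey covariates are extracted at the
  # cluster coordinate), then expanded to households
  cols <- list(); std <- list(); surfaces <- list()
  for (cv in config$covariate_spec) {
    if (cv$kind == "continuous") {
      sf <- draw_surface(cv$trend_sd)
      val <- eval_surface(sf, cl_lon, cl_lat, dom) +
        stats::rnorm(nc, 0, cv$noise_sd)
      m <- mean(val[cl_of]); s <- stats::sd(val[cl_of])
      cols[[cv$name]] <- standardize(val, m, s)
      std[[cv$name]] <- c(mean = m, sd = s)
      surfaces[[cv$name]] <- c(sf, list(noise_sd = cv$noise_sd))
    } else if (cv$kind == "time") {
      dr <- as.Date(cv$date_range)
      day0 <- as.numeric(dr - as.Date("2005-01-01"))
      days <- stats::runif(nc, day0[1], day0[2])
      val <- log(pmax(days, 1))
      m <- mean(val[cl_of]); s <- stats::sd(val[cl_of])
      cols[[cv$name]] <- standardize(val, m, s)
      std[[cv$name]] <- c(mean = m, sd = s)
    } else if (cv$kind == "categorical") {
      lev <- cv$levels
      pr <- if (is.null(cv$probs)) rep(1 / length(lev), length(lev)) else cv$probs
      val <- sample(lev, nc, replace = TRUE, prob = pr)
      for (lv in lev[-1])
        cols[[paste0(cv$name, "_", lv)]] <- as.numeric(val == lv)
      surfaces[[cv$name]] <- list(levels = lev, probs = pr)
    } else stop("unknown covariate kind: ", cv$kind, call. = FALSE)
  }
  X_cl <- do.call(cbind, cols)
  design <- names(cols)

  b <- stats::rnorm(nc, 0, config$sigma_b)
  u <- if (config$sigma_u > 0)
    sample_grf(cbind(cl_lon, cl_lat), config$spatial_range, config$sigma_u)
  else numeric(nc)

  X <- X_cl[cl_of, , drop = FALSE]
  z <- drop(X %*% config$beta) + u[cl_of] + b[cl_of]
  probs <- class_probabilities(z, config$thresholds)
  yr <- stats::runif(n)
  cum <- row_cumsum(probs)
  cum[, config$K] <- 1
  y <- max.col(yr < cum, ties.method = "first") - 1L

  households <- data.frame(household_id = seq_len(n), cluster_id = cl_of,
                           lon = cl_lon[cl_of], lat = cl_lat[cl_of])
  households <- cbind(households, as.data.frame(X))
  households$y <- y
  clusters <- data.frame(cluster_id = seq_len(nc), lon = cl_lon, lat = cl_lat,
                         n_households = n_hh)
  standardization <- if (length(std))
    data.frame(name = names(std),
               mean = vapply(std, `[[`, numeric(1), "mean"),
               sd = vapply(std, `[[`, numeric(1), "sd"),
               row.names = NULL)
  else data.frame(name = character(), mean = numeric(), sd = numeric())

  structure(list(households = households, clusters = clusters,
                 design = design, K = config$K,
                 standardization = standardization,
                 truth = list(b = b, u = u, z = z, probs = probs),
                 surfaces = surfaces, config = config),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("survey_dataset:", nrow(x$households), "households in",
      nrow(x$clusters), "clusters;", x$K, "outcome categories\n")
  cat("design columns:", paste(x$design, collapse = ", "), "\n")
  print(table(y = x$households$y))
  invisible(x)
}

#' Regular prediction grid with covariate layers
#'
#' Builds a regular lon/lat grid of cell centres over a bounding box and
#' populates covariate layers. Continuous covariates reuse the survey's
#' generating surfaces when a `survey_dataset` is supplied (plus fresh local
#' noise), and every layer is standardized with the *training* means/SDs,
#' never the grid's own. A time covariate is filled with
#' `time_covariate(date)`, standardized the same way.
#'
#' @param domain Bounding box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param resolution Cell size in degrees (default 0.05, the production grid
#'   spacing).
#' @param data A `survey_dataset` providing covariate surfaces,
#'   standardization statistics and the covariate spec.
#' @param date Prediction date for the time covariate (default
#'   `"2024-01-01"`).
#' @param seed Integer seed for the grid's local covariate noise.
#' @return Object of class `prediction_grid`: `lon_axis`, `lat_axis` (cell
#'   centres, ascending), `layers` (named list of `n_lon x n_lat` matrices),
#'   `resolution`, `domain`.
#' @export
make_prediction_grid <- function(domain, resolution = 0.05, data,
                                 date = "2024-01-01", seed = 1L) {
  stopifnot(resolution > 0, inherits(data, "survey_dataset"))
  if (domain[2] - domain[1] < resolution || domain[4] - domain[3] < resolution)
    stop("empty grid: domain smaller than one cell", call. = FALSE)
  lon_axis <- seq(domain[1] + resolution / 2, domain[2] - resolution / 2,
                  by = resolution)
  lat_axis <- seq(domain[3] + resolution / 2, domain[4] - resolution / 2,
                  by = resolution)
  set.seed(as.integer(seed))
  nx <- length(lon_axis); ny <- length(lat_axis)
  lon <- rep(lon_axis, times = ny); lat <- rep(lat_axis, each = nx)
  std <- data$standardization
  layers <- list()
  for (cv in data$config$covariate_spec) {
    if (cv$kind == "continuous") {
      sf <- data$surfaces[[cv$name]]
      val <- eval_surface(sf, lon, lat, data$config$domain) +
        stats::rnorm(nx * ny, 0, sf$noise_sd)
      i <- match(cv$name, std$name)
      layers[[cv$name]] <- matrix(standardize(val, std$mean[i], std$sd[i]),
                                  nx, ny)
    } else if (cv$kind == "time") {
      i <- match(cv$name, std$name)
      val <- standardize(time_covariate(date), std$mean[i], std$sd[i])
      layers[[cv$name]] <- matrix(val, nx, ny)
    } else if (cv$kind == "categorical") {
      sp <- data$surfaces[[cv$name]]
      val <- sample(sp$levels, nx * ny, replace = TRUE, prob = sp$probs)
      for (lv in sp$levels[-1])
        layers[[paste0(cv$name, "_", lv)]] <-
          matrix(as.numeric(val == lv), nx, ny)
    }
  }
  structure(list(lon_axis = lon_axis, lat_axis = lat_axis, layers = layers,
                 resolution = resolution, domain = as.numeric(domain),
                 date = as.character(date)),
            class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat("prediction_grid:", length(x$lon_axis), "x", length(x$lat_axis),
      "cells at", x$resolution, "deg; layers:",
      paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write survey datasets as CSV with a YAML sidecar
#'
#' The household table goes to `<path>.csv`, the cluster table to
#' `<path>_clusters.csv` and the metadata (K, design columns,
#' standardization statistics, covariate spec) to `<path>.yaml`, keeping the
#' on-disk form plain text and diffable. The simulation `truth` block is not
#' serialized.
#'
#' @param data A `survey_dataset`.
#' @param path Base path (without extension).
#' @return `write_survey` returns the paths invisibly; `read_survey` the
#'   reconstructed `survey_dataset` (without `truth`).
#' @export
write_survey <- function(data, path) {
  stopifnot(inherits(data, "survey_dataset"))
  pc <- paste0(path, ".csv"); pk <- paste0(path, "_clusters.csv")
  py <- paste0(path, ".yaml")
  utils::write.csv(data$households, pc, row.names = FALSE)
  utils::write.csv(data$clusters, pk, row.names = FALSE)
  meta <- list(K = data$K, design = as.list(data$design),
               standardization = lapply(seq_len(nrow(data$standardization)),
                 function(i) as.list(data$standardization[i, ])),
               config = config_to_list(data$config))
  yaml::write_yaml(meta, py, precision = 15)
  invisible(c(pc, pk, py))
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  households <- utils::read.csv(paste0(path, ".csv"))
  clusters <- utils::read.csv(paste0(path, "_clusters.csv"))
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  std <- if (length(meta$standardization))
    do.call(rbind, lapply(meta$standardization, as.data.frame))
  else data.frame(name = character(), mean = numeric(), sd = numeric())
  structure(list(households = households, clusters = clusters,
                 design = unlist(meta$design), K = meta$K,
                 standardization = std, truth = NULL,
                 surfaces = NULL, config = config_from_list(meta$config)),
            class = "survey_dataset")
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$covariate_spec <- lapply(out$covariate_spec, function(cv) {
    if (!is.null(cv$date_range)) cv$date_range <- as.character(cv$date_range)
    cv
  })
  out
}

config_from_list <- function(lst) {
  lst$covariate_spec <- lapply(lst$covariate_spec, function(cv) {
    if (!is.null(cv$date_range)) cv$date_range <- as.Date(unlist(cv$date_range))
    cv
  })
  lst$beta <- as.numeric(unlist(lst$beta))
  lst$thresholds <- as.numeric(unlist(lst$thresholds))
  lst$domain <- as.numeric(unlist(lst$domain))
  lst$households_per_cluster <- as.integer(unlist(lst$households_per_cluster))
  do.call(survey_config, lst[c("n_clusters", "households_per_cluster", "K",
                               "beta", "thresholds", "sigma_b",
                               "spatial_range", "sigma_u", "domain",
                               "covariate_spec", "seed")])
}
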