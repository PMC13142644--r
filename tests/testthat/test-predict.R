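# small fitted model + grid shared within this file
pred_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- survey_config(n_clusters = 60, households_per_cluster = c(15, 20),
                           K = 3, beta = c(0.8, -0.5, 0.3),
                           thresholds = c(-0.5, 1.5), domain = c(30, 32, -2, 0),
                           spatial_range = 1, seed = 52)
      dat <- simulate_survey(cfg)
      fit <- spatord(data = dat)
      grid <- make_prediction_grid(c(30, 32, -2, 0), resolution = 0.2,
                                   data = dat, seed = 51)
      cache <<- list(cfg = cfg, dat = dat, fit = fit, grid = grid)
    }
    cache
  }
})

test_that("probability surfaces are coherent with the cumulative-logit model", {
  fx <- pred_fixture()
  surf <- predict_grid(fx$fit, fx$grid)
  P <- sapply(surf$prob, as.vector)
  valid <- as.vector(surf$mask)
  expect_true(any(valid))
  expect_true(all(abs(rowSums(P[valid, ]) - 1) < 1e-12))
  expect_true(all(P[valid, ] >= 0 & P[valid, ] <= 1))
  expect_true(all(is.nan(P[!valid, ])))
  # probabilities equal the per-cell recomputation from the latent mean
  nx <- length(fx$grid$lon_axis); ny <- length(fx$grid$lat_axis)
  lon <- rep(fx$grid$lon_axis, times = ny); lat <- rep(fx$grid$lat_axis, each = nx)
  X <- sapply(fx$fit$design, function(nm) as.vector(fx$grid$layers[[nm]]))
  A <- suppressWarnings(projection_matrix(fx$fit$mesh, cbind(lon, lat)))
  z <- drop(X %*% fx$fit$params$beta) + drop(A %*% fx$fit$re_mode$w)
  P2 <- class_probabilities(z, fx$fit$params$thresholds)
  expect_equal(P[valid, ], P2[valid, ], tolerance = 1e-12, ignore_attr = TRUE)
  # cumulative sums reproduce sigma(theta_k - z)
  cum <- t(apply(P[valid, ], 1, cumsum))[, 1:2]
  expect_equal(cum, plogis(outer(-z[valid], fx$fit$params$thresholds, `+`)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # missing covariate layer is reported by name
  g2 <- fx$grid; g2$layers$hdi <- NULL
  expect_error(predict_grid(fx$fit, g2), "hdi")
})

test_that("delta-method standard errors follow the closed form", {
  # K = 2, p = 0.5 (z at the threshold), sd(z) = 0.1: SE = 0.25 * 0.1
  dz <- spatord:::class_prob_dz(0, 0)
  expect_equal(abs(dz[1, ]) * 0.1, c(0.025, 0.025), ignore_attr = TRUE)
  fx <- pred_fixture()
  surf <- predict_grid(fx$fit, fx$grid, se = TRUE)
  S <- sapply(surf$se, as.vector)
  valid <- as.vector(surf$mask)
  expect_true(all(S[valid, ] >= 0))
  # with both uncertainty components off, every SE is exactly zero
  s0 <- predict_grid(fx$fit, fx$grid, se = TRUE,
                     include_spatial_uncertainty = FALSE,
                     include_fixed_uncertainty = FALSE)
  expect_true(all(sapply(s0$se, function(m) all(m[surf$mask] == 0))))
  # SE layers equal |dp_k/dz| * sd(z*) recomputed per cell
  nx <- length(fx$grid$lon_axis); ny <- length(fx$grid$lat_axis)
  lon <- rep(fx$grid$lon_axis, times = ny); lat <- rep(fx$grid$lat_axis, each = nx)
  X <- sapply(fx$fit$design, function(nm) as.vector(fx$grid$layers[[nm]]))
  A <- suppressWarnings(projection_matrix(fx$fit$mesh, cbind(lon, lat)))
  z <- drop(X %*% fx$fit$params$beta) + drop(A %*% fx$fit$re_mode$w)
  dpk <- abs(spatord:::class_prob_dz(z, fx$fit$params$thresholds))
  for (k in seq_len(fx$fit$K))
    expect_equal(as.vector(surf$se[[k]])[valid],
                 (dpk[, k] * as.vector(surf$sd_link))[valid],
                 tolerance = 1e-10)
})

test_that("GeoTIFF rasters follow the naming convention and round-trip bit-exactly", {
  fx <- pred_fixture()
  surf <- predict_grid(fx$fit, fx$grid)
  out <- file.path(tempdir(), "rasters_test")
  unlink(out, recursive = TRUE)
  classes <- c("UnimpW_Srf", "UnimpW_Oth", "ImpW_Pipe")
  paths <- write_rasters(surf, "water", classes, out)
  expect_setequal(basename(paths),
                  c("water_prob_UnimpW_Srf.tif", "water_se_UnimpW_Srf.tif",
                    "water_prob_UnimpW_Oth.tif", "water_se_UnimpW_Oth.tif",
                    "water_prob_ImpW_Pipe.tif", "water_se_ImpW_Pipe.tif"))
  # overwrite protection
  expect_error(write_rasters(surf, "water", classes, out), "overwrite")
  r1 <- read_geotiff(file.path(out, "water_prob_ImpW_Pipe.tif"))
  expect_equal(r1$crs, 4326L)
  expect_equal(dim(r1$values),
               c(length(fx$grid$lat_axis), length(fx$grid$lon_axis)))
  expect_equal(r1$pixel_size, c(0.2, 0.2), tolerance = 1e-12)
  expect_equal(r1$origin, c(30, 0), tolerance = 1e-12)
  # float32 round trip: rewriting what was read reproduces bytes exactly
  f2 <- file.path(out, "rewrite.tif")
  write_geotiff(r1$values, f2, r1$origin, r1$pixel_size)
  r2 <- read_geotiff(f2)
  expect_identical(r2$values, r1$values)
  expect_identical(r2$origin, r1$origin)
  expect_identical(r2$pixel_size, r1$pixel_size)
  # 0.05 degree grid over 1x1 degree -> 20 x 20 raster
  g <- make_prediction_grid(c(30, 31, -2, -1), resolution = 0.05,
                            data = fx$dat, seed = 1)
  expect_equal(dim(predict_grid(fx$fit, g, se = FALSE)$prob[[1]]), c(20L, 20L))
})

test_that("newdata predictions and argmax classes are consistent", {
  fx <- pred_fixture()
  nd <- fx$dat$households[1:30, ]
  p <- predict(fx$fit, newdata = nd)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  cl <- predict(fx$fit, newdata = nd, type = "class")
  expect_equal(cl, max.col(p, ties.method = "first") - 1L)
  z <- predict(fx$fit, newdata = nd, type = "link")
  expect_equal(p, class_probabilities(z, fx$fit$params$thresholds),
               tolerance = 1e-12)
})

test_that("fitted models round-trip through the plain-text container", {
  fx <- pred_fixture()
  dir <- file.path(tempdir(), "model_container")
  write_model(fx$fit, dir, overwrite = TRUE)
  m2 <- read_model(dir)
  expect_equal(m2$par, fx$fit$par, tolerance = 1e-12)
  expect_equal(m2$re_mode$w, fx$fit$re_mode$w, tolerance = 1e-12)
  expect_equal(as.matrix(m2$param_cov), as.matrix(fx$fit$param_cov),
               tolerance = 1e-10, ignore_attr = TRUE)
  # the reloaded model predicts identically (probabilities and SEs)
  s1 <- predict_grid(fx$fit, fx$grid)
  s2 <- predict_grid(m2, fx$grid)
  expect_equal(s2$prob, s1$prob, tolerance = 1e-9)
  expect_equal(s2$se, s1$se, tolerance = 1e-7)
  expect_error(write_model(fx$fit, dir), "overwrite")
  unlink(dir, recursive = TRUE)
})
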