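test_that("survey config enforces its invariants", {
  expect_error(survey_config(K = 6), "at most five")
  expect_error(survey_config(K = 1), "between 2 and 5")
  expect_error(survey_config(thresholds = c(1, 0, 2)), "increasing")
  expect_error(survey_config(thresholds = c(-1, 0)), "length")
  expect_error(survey_config(households_per_cluster = c(30, 25)), "low, high")
  expect_error(survey_config(households_per_cluster = c(0, 10)), "1, 1000")
  expect_error(survey_config(beta = c(1, 2)), "design columns")
  expect_error(survey_config(sigma_b = -1), "nonnegative")
  expect_error(survey_config(spatial_range = 0), "> 0")
})

test_that("time covariate is the log day count since 2005-01-01", {
  expect_equal(time_covariate("2005-01-02"), 0)
  expect_equal(time_covariate("2024-01-01"), log(6939), tolerance = 1e-12)
  expect_equal(time_covariate("2006-01-01"), log(365), tolerance = 1e-12)
  expect_error(time_covariate("2005-01-01"), "after")
  expect_error(time_covariate("2004-12-25"), "after")
})

test_that("simulated surveys satisfy the generative contracts", {
  cfg <- survey_config(n_clusters = 60, seed = 31)
  d <- simulate_survey(cfg)
  hh <- d$households
  # households inherit their cluster's coordinates and the domain bounds
  expect_true(all(hh$cluster_id %in% d$clusters$cluster_id))
  expect_equal(hh$lon, d$clusters$lon[hh$cluster_id])
  expect_true(all(hh$lon >= cfg$domain[1] & hh$lon <= cfg$domain[2]))
  expect_true(all(hh$lat >= cfg$domain[3] & hh$lat <= cfg$domain[4]))
  expect_true(all(hh$y %in% 0:(cfg$K - 1)))
  expect_true(all(d$clusters$n_households >= 25 &
                  d$clusters$n_households <= 30))
  # standardization invariant over the training set
  for (nm in c("hdi", "night", "time")) {
    expect_lt(abs(mean(hh[[nm]])), 1e-8)
    expect_lt(abs(sd(hh[[nm]]) - 1), 1e-8)
  }
  # determinism: same config, identical dataset
  expect_identical(d, simulate_survey(cfg))
})

test_that("generated categories follow the latent cumulative-logit model", {
  # sigma_b = sigma_u = 0, beta = 0: category frequencies are the logistic
  # band probabilities (0.2689, 0.4621, 0.2689) for thresholds (-1, 1)
  cfg <- survey_config(n_clusters = 3600, households_per_cluster = c(28, 28),
                       K = 3, beta = c(0, 0, 0), thresholds = c(-1, 1),
                       sigma_b = 0, sigma_u = 0, seed = 32)
  d <- simulate_survey(cfg)
  n <- nrow(d$households)
  expect_gte(n, 1e5)
  freq <- tabulate(d$households$y + 1L, 3) / n
  expected <- c(plogis(-1), plogis(1) - plogis(-1), plogis(-1))
  mc_se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(freq - expected) < 3 * mc_se))
  # self-consistency with the retained truth probabilities
  expect_lt(max(abs(freq - colMeans(d$truth$probs))), 0.01)
})

test_that("standardize and destandardize are exact inverses", {
  x <- rnorm(100, 7, 3)
  expect_equal(destandardize(standardize(x, 7, 3), 7, 3), x,
               tolerance = 1e-12)
})

test_that("prediction grids have the right geometry and reuse training statistics", {
  cfg <- survey_config(n_clusters = 40, domain = c(30, 31, -1, 0), seed = 33,
                       spatial_range = 0.4)
  d <- simulate_survey(cfg)
  g <- make_prediction_grid(c(30, 31, -1, 0), resolution = 0.05, data = d,
                            seed = 7)
  expect_equal(length(g$lon_axis), 20L)
  expect_equal(length(g$lat_axis), 20L)
  expect_equal(length(g$lon_axis) * length(g$lat_axis), 400L)
  # time layer is an affine map of the constant prediction-date covariate
  i <- match("time", d$standardization$name)
  expect_equal(unique(as.vector(g$layers$time)),
               (time_covariate("2024-01-01") - d$standardization$mean[i]) /
                 d$standardization$sd[i])
  # determinism
  g2 <- make_prediction_grid(c(30, 31, -1, 0), resolution = 0.05, data = d,
                             seed = 7)
  expect_identical(g, g2)
  expect_error(make_prediction_grid(c(30, 30.01, -1, 0), resolution = 0.05,
                                    data = d), "empty")
})

test_that("survey datasets round-trip through CSV + YAML", {
  cfg <- survey_config(n_clusters = 15, seed = 34)
  d <- simulate_survey(cfg)
  base <- file.path(tempdir(), "rt_survey")
  write_survey(d, base)
  d2 <- read_survey(base)
  expect_equal(d2$households$y, d$households$y)
  expect_equal(d2$households$hdi, d$households$hdi, tolerance = 1e-12)
  expect_equal(d2$K, d$K)
  expect_equal(d2$design, d$design)
  expect_equal(d2$standardization$mean, d$standardization$mean,
               tolerance = 1e-12)
  unlink(paste0(base, c(".csv", "_clusters.csv", ".yaml")))
})
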