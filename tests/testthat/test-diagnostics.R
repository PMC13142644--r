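test_that("Dunn-Smyth residuals are valid randomized quantile residuals", {
  set.seed(60)
  # degenerate K = 2 interval with P(y = 1) = 1: u ~ U(0,1), r ~ N(0,1)
  n <- 20000
  probs <- cbind(rep(0, n), rep(1, n))
  r <- dunn_smyth_residuals(probs, rep(1L, n), seed = 61)
  expect_lt(abs(mean(r)), 0.03)
  expect_lt(abs(sd(r) - 1), 0.03)
  # determinism
  expect_identical(r, dunn_smyth_residuals(probs, rep(1L, n), seed = 61))
  # under the true generative probabilities the residuals are standard normal
  th <- c(-1, 0.5, 2)
  z <- rnorm(n, 0, 1.2)
  P <- class_probabilities(z, th)
  cum <- t(apply(P, 1, cumsum)); cum[, 4] <- 1
  y <- max.col(runif(n) < cum, ties.method = "first") - 1L
  r2 <- dunn_smyth_residuals(P, y, seed = 62)
  expect_lt(abs(mean(r2)), 0.03)
  expect_lt(abs(sd(r2) - 1), 0.03)
  expect_gt(suppressWarnings(ks.test(r2, "pnorm"))$p.value, 0.01)
  # invalid rows rejected
  expect_error(dunn_smyth_residuals(cbind(0.4, 0.4), c(0L), seed = 1), "sum")
})

test_that("calibration tables partition the data and track true rates", {
  set.seed(63)
  n <- 50000
  # constant prediction 0.3 against outcomes at true rate 0.3
  probs <- cbind(rep(0.7, n), rep(0.3, n))
  y <- rbinom(n, 1, 0.3)
  cal <- calibration_curve(probs, y, n_bins = 10)
  expect_equal(sum(cal$count[cal$class == 1L]), n)
  row <- cal[cal$class == 1L & cal$count > 0, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$mean_predicted, 0.3, tolerance = 1e-12)
  expect_equal(row$observed_frequency, 0.3, tolerance = 0.02)
  # empty bins are flagged, not dropped
  expect_equal(sum(cal$class == 1L), 10L)
  expect_true(any(cal$empty))
  expect_error(calibration_curve(probs, y, n_bins = 1), "n_bins")
})

test_that("classification metrics match brute-force oracles", {
  # frozen examples
  m1 <- classification_metrics(cbind(1 - c(0.9, 0.8, 0.3, 0.1),
                                     c(0.9, 0.8, 0.3, 0.1)),
                               c(1L, 0L, 1L, 0L))
  expect_equal(m1$auc[2], 0.75)          # brute force over the 4 pairs
  expect_equal(m1$support, c(2L, 2L))
  ps <- cbind(c(0.1, 0.2), c(0.9, 0.8))
  expect_equal(classification_metrics(ps, c(0L, 1L))$auc[2], 0)
  expect_equal(classification_metrics(ps, c(1L, 0L))$auc[2], 1)
  expect_equal(classification_metrics(cbind(rep(0.5, 6), rep(0.5, 6)),
                                      rep(c(0L, 1L), 3))$auc[2], 0.5)
  # rank AUC equals exhaustive pairwise comparison (with tie midranks)
  set.seed(64)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    K <- sample(2:4, 1)
    P <- matrix(rexp(n * K), n); P <- P / rowSums(P)
    P <- round(P, 2)  # force ties
    y <- sample(0:(K - 1), n, replace = TRUE)
    got <- classification_metrics(P, y)
    for (k in seq_len(K)) {
      pos <- which(y == k - 1L); neg <- which(y != k - 1L)
      if (!length(pos) || !length(neg)) next
      cmp <- outer(P[pos, k], P[neg, k], function(a, b)
        (a > b) + 0.5 * (a == b))
      expect_equal(got$auc[k], mean(cmp))
    }
  }
  # cross-check against an independent implementation
  set.seed(65)
  sc <- runif(150); yy <- rbinom(150, 1, plogis(3 * sc - 1.5))
  ours <- classification_metrics(cbind(1 - sc, sc), yy)$auc[2]
  ref <- as.numeric(suppressMessages(pROC::auc(yy, sc)))
  expect_equal(ours, ref, tolerance = 1e-10)
  # single observed class: flagged undefined
  und <- classification_metrics(cbind(c(0.6, 0.7), c(0.4, 0.3)), c(0L, 0L))
  expect_true(und$undefined[2])
  expect_true(is.na(und$auc[2]))
})

test_that("Shapley attributions decompose the linear predictor exactly", {
  set.seed(66)
  X <- matrix(rnorm(200 * 3), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(1.5, -2, 0.3)
  sh <- shap_linear(beta, X)
  eta <- drop(X %*% beta)
  expect_lt(max(abs(rowSums(sh$attributions) - (eta - mean(eta)))), 1e-10)
  # x at the background mean: all attributions zero
  sh0 <- shap_linear(beta, matrix(colMeans(X), 1, 3), colMeans(X))
  expect_equal(as.numeric(sh0$attributions), c(0, 0, 0))
  # doubling a coefficient doubles its column exactly
  sh2 <- shap_linear(beta * c(2, 1, 1), X)
  expect_equal(sh2$attributions[, 1], 2 * sh$attributions[, 1])
  expect_equal(sh2$attributions[, 2], sh$attributions[, 2])
  expect_error(shap_linear(beta, X[, 1:2]), "ncol")
})

test_that("posterior predictive replicates are deterministic and coherent", {
  cfg <- survey_config(n_clusters = 40, households_per_cluster = c(10, 12),
                       K = 3, beta = c(0.8, -0.5, 0.3),
                       thresholds = c(-0.5, 1.5), seed = 67)
  dat <- simulate_survey(cfg)
  fit <- spatord(data = dat, spatial = FALSE)
  p1 <- posterior_predictive_check(fit, n_rep = 1, seed = 5)
  p2 <- posterior_predictive_check(fit, n_rep = 1, seed = 5)
  expect_identical(p1, p2)
  expect_equal(sum(p1$table$observed), 1, tolerance = 1e-12)
  expect_equal(sum(p1$table$replicate_mean), 1, tolerance = 1e-12)
  pp <- posterior_predictive_check(fit, n_rep = 30, seed = 6)
  # correctly specified fit reproduces its own category frequencies
  expect_lt(pp$max_abs_diff, 0.05)
  # sanity direction: dropping the strongest covariate cannot improve the
  # match between observed and replicate frequencies
  fit_bad <- spatord(y ~ night, data = dat, spatial = FALSE)
  pb <- posterior_predictive_check(fit_bad, n_rep = 30, seed = 6)
  expect_gt(pb$max_abs_diff, pp$max_abs_diff)
})

test_that("the diagnostics report bundles and serializes every component", {
  cfg <- survey_config(n_clusters = 40, households_per_cluster = c(10, 12),
                       K = 3, beta = c(0.8, -0.5, 0.3),
                       thresholds = c(-0.5, 1.5), seed = 68)
  dat <- simulate_survey(cfg)
  fit <- spatord(data = dat, spatial = FALSE)
  rep <- diagnose(fit, n_rep = 20, seed = 9)
  expect_s3_class(rep, "spatord_diagnostics")
  expect_equal(length(rep$residuals), nrow(dat$households))
  expect_equal(sum(rep$metrics$support), nrow(dat$households))
  expect_true(all(c("mean", "sd", "skewness", "ks_statistic") %in%
                  names(rep$residual_summary)))
  out <- file.path(tempdir(), "diag_out")
  unlink(out, recursive = TRUE)
  paths <- write_diagnostics(rep, out)
  expect_true(all(file.exists(paths)))
  js <- paste(readLines(file.path(out, "summary.json")), collapse = "")
  expect_match(js, "ppc_max_abs_diff")
})
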