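test_that("joint NLL matches a naive dense re-implementation", {
  set.seed(40)
  cfg <- survey_config(n_clusters = 6, households_per_cluster = c(5, 5),
                       seed = 40)
  d <- simulate_survey(cfg)
  mesh <- build_mesh(as.matrix(d$clusters[, c("lon", "lat")]),
                     buffer_fraction = 0.3)
  params <- list(beta = c(0.5, -0.3, 0.2), theta1 = -1,
                 log_deltas = c(0.2, 0.1), log_sigma_b = log(0.6),
                 log_range = log(1.4), log_sigma_u = log(0.8))
  re <- list(b = rnorm(6, 0, 0.3), w = rnorm(nrow(mesh$nodes), 0, 0.3))
  got <- joint_nll(params, re, d, mesh)

  # independent dense computation
  th <- thresholds_from_raw(params$theta1, params$log_deltas)
  X <- as.matrix(d$households[, d$design])
  A <- as.matrix(projection_matrix(mesh, as.matrix(d$clusters[, c("lon", "lat")])))
  cl <- d$households$cluster_id
  z <- drop(X %*% params$beta) + (A %*% re$w)[cl] + re$b[cl]
  P <- class_probabilities(z, th)
  ll_ord <- sum(log(P[cbind(seq_len(nrow(P)), d$households$y + 1L)]))
  ll_b <- sum(dnorm(re$b, 0, 0.6, log = TRUE))
  Q <- as.matrix(precision_matrix(mesh, 1.4, 0.8))
  m <- nrow(Q)
  ll_w <- -m / 2 * log(2 * pi) + 0.5 * determinant(Q)$modulus -
    0.5 * drop(re$w %*% Q %*% re$w)
  expect_equal(got, -(ll_ord + ll_b + as.numeric(ll_w)), tolerance = 1e-8)

  # Gaussian cluster term at the origin is its normalising constant
  p0 <- list(beta = c(0, 0, 0), theta1 = 0, log_deltas = c(0, 0),
             log_sigma_b = 0)
  re0 <- list(b = rep(0, 6))
  base <- sum(ordinal_nll(d$households$y, 0, thresholds_from_raw(0, c(0, 0))))
  expect_equal(joint_nll(p0, re0, d) - base, 6 / 2 * log(2 * pi),
               tolerance = 1e-10)
})

test_that("latent location shifts move thresholds, not the data term", {
  # adding a constant to z and to every threshold leaves the likelihood alone
  set.seed(41)
  y <- sample(0:2, 40, replace = TRUE)
  z <- rnorm(40)
  th <- c(-0.5, 1)
  expect_equal(ordinal_nll(y, z + 2.3, th + 2.3), ordinal_nll(y, z, th),
               tolerance = 1e-10)
})

test_that("inner Newton finds the conditional mode", {
  cfg <- survey_config(n_clusters = 25, households_per_cluster = c(10, 14),
                       sigma_u = 0, seed = 42)
  d <- simulate_survey(cfg)
  params <- list(beta = cfg$beta, theta1 = -1,
                 log_deltas = c(log(1.5), log(1.5)), log_sigma_b = log(0.5))
  im <- inner_mode(params, d, tol = 1e-10)
  expect_lt(im$gnorm, 1e-10)
  # mode invariant to household row permutation
  set.seed(43)
  perm <- sample(nrow(d$households))
  d2 <- d; d2$households <- d$households[perm, ]
  im2 <- inner_mode(params, d2, tol = 1e-10)
  expect_equal(im2$b, im$b, tolerance = 1e-8)
  # near-flat prior: mode approaches the per-cluster 1-D ML offsets
  params_flat <- params; params_flat$log_sigma_b <- log(50)
  imf <- inner_mode(params_flat, d)
  th <- thresholds_from_raw(params$theta1, params$log_deltas)
  X <- as.matrix(d$households[, d$design])
  eta <- drop(X %*% cfg$beta)
  for (cc in c(1, 7, 19)) {
    idx <- d$households$cluster_id == cc
    oracle <- optimize(function(b)
      sum(ordinal_nll(d$households$y[idx], eta[idx] + b, th)),
      c(-8, 8))$minimum
    expect_equal(imf$b[cc], oracle, tolerance = 0.01)
  }
})

test_that("inner Newton trajectory is non-increasing", {
  cfg <- survey_config(n_clusters = 30, seed = 44)
  d <- simulate_survey(cfg)
  params <- list(beta = cfg$beta, theta1 = -1,
                 log_deltas = c(log(1.5), log(1.5)), log_sigma_b = log(0.5),
                 log_range = log(1.5), log_sigma_u = log(0.75))
  st <- spatord:::structure_from_dataset(d, NULL, TRUE, TRUE)
  up <- spatord:::params_to_unpacked(params, st)
  Q <- precision_matrix(st$mesh, up$range, up$sigma_u)
  ld <- spatord:::logdet_ch(spatord:::chol_update(st, "ch_Q", Q))
  im <- spatord:::inner_newton(st, up, Q, ld)
  expect_true(all(diff(im$trajectory) <= 1e-9))
})

test_that("Laplace approximation agrees with quadrature oracles", {
  # 1 household, K = 2, theta = 0, sigma_b = 1: exact marginal prob is 0.5
  d1 <- tiny_dataset(y = c(0L, 1L))
  params <- list(beta = 0, theta1 = 0, log_deltas = numeric(0),
                 log_sigma_b = 0)
  nll <- laplace_marginal_nll(params, d1)
  # per-household marginal probability within 2% of 0.5
  expect_equal(exp(-nll / 2), 0.5, tolerance = 0.02)

  # 5-cluster cluster-effect-only instance vs adaptive and Gauss-Hermite
  # quadrature: relative error < 1e-3
  cfg <- survey_config(n_clusters = 5, households_per_cluster = c(8, 8),
                       sigma_b = 0.7, sigma_u = 0, seed = 45)
  d5 <- simulate_survey(cfg)
  p5 <- list(beta = c(0.6, -0.4, 0.2), theta1 = -1,
             log_deltas = c(log(1.5), log(1.5)), log_sigma_b = log(0.7))
  lap <- laplace_marginal_nll(p5, d5)
  th <- thresholds_from_raw(p5$theta1, p5$log_deltas)
  X <- as.matrix(d5$households[, d5$design])
  eta <- drop(X %*% p5$beta)
  quad_adapt <- 0
  quad_gh <- 0
  gh <- pracma::gaussHermite(61)
  for (cc in 1:5) {
    idx <- d5$households$cluster_id == cc
    condl <- function(b) vapply(b, function(bb)
      exp(-sum(ordinal_nll(d5$households$y[idx], eta[idx] + bb, th))),
      numeric(1))
    quad_adapt <- quad_adapt -
      log(integrate(function(b) condl(b) * dnorm(b, 0, 0.7), -5, 5,
                    rel.tol = 1e-12)$value)
    # int f(b) phi(b; 0, s) db = (1/sqrt(pi)) sum w_i f(sqrt(2) s x_i)
    quad_gh <- quad_gh -
      log(sum(gh$w * condl(sqrt(2) * 0.7 * gh$x)) / sqrt(pi))
  }
  expect_equal(lap, quad_adapt, tolerance = 1e-3)
  expect_equal(lap, quad_gh, tolerance = 1e-3)

  # sigma_b -> 0: marginal NLL collapses to the fixed-effects ordinal NLL
  p_small <- p5; p_small$log_sigma_b <- log(1e-6)
  fe <- sum(ordinal_nll(d5$households$y, eta, th))
  expect_equal(laplace_marginal_nll(p_small, d5), fe, tolerance = 1e-4)
})

test_that("fixed-effects-only fit reproduces the proportional-odds ML fit", {
  cfg <- survey_config(n_clusters = 80, sigma_b = 0, sigma_u = 0, seed = 46)
  d <- simulate_survey(cfg)
  f <- spatord(y ~ hdi + night + time, data = d, spatial = FALSE,
               cluster_re = FALSE)
  pf <- MASS::polr(factor(y) ~ hdi + night + time, data = d$households,
                   method = "logistic")
  expect_equal(unname(f$params$beta), unname(coef(pf)), tolerance = 1e-3)
  expect_equal(unname(f$params$thresholds), unname(pf$zeta), tolerance = 1e-3)
  # beta within 3 reported SEs of the simulation truth
  se <- sqrt(diag(f$param_cov))[1:3]
  expect_true(all(abs(f$params$beta - cfg$beta) < 3 * se))
  # refits are identical: the fit is deterministic
  f2 <- spatord(y ~ hdi + night + time, data = d, spatial = FALSE,
                cluster_re = FALSE)
  expect_equal(f$par, f2$par, tolerance = 1e-8)
})

test_that("thresholds absorb location and coefficients rescale with covariates", {
  cfg <- survey_config(n_clusters = 70, sigma_b = 0, sigma_u = 0, seed = 47)
  d <- simulate_survey(cfg)
  f0 <- spatord(data = d, spatial = FALSE, cluster_re = FALSE)
  # there is no intercept column: adding a constant to a covariate column is
  # an intercept shift, absorbed exactly by the thresholds, never by beta
  ds <- d
  ds$households$hdi <- d$households$hdi + 2
  fs <- spatord(data = ds, spatial = FALSE, cluster_re = FALSE)
  expect_equal(fs$params$beta, f0$params$beta, tolerance = 1e-2)
  expect_equal(fs$params$thresholds,
               f0$params$thresholds + 2 * f0$params$beta[["hdi"]],
               tolerance = 1e-2)
  # rescaling a covariate column by c divides its coefficient by c
  d2 <- d
  d2$households$hdi <- d$households$hdi * 4
  f4 <- spatord(data = d2, spatial = FALSE, cluster_re = FALSE)
  expect_equal(f4$params$beta[["hdi"]], f0$params$beta[["hdi"]] / 4,
               tolerance = 1e-2)
  expect_equal(f4$params$beta[["night"]], f0$params$beta[["night"]],
               tolerance = 1e-2)
})

test_that("degenerate data are rejected with actionable errors", {
  cfg <- survey_config(n_clusters = 10, seed = 48)
  d <- simulate_survey(cfg)
  d$households$y[d$households$y == 3L] <- 2L  # category 3 unobserved
  expect_error(spatord(data = d), "merge")
  d2 <- simulate_survey(cfg)
  d2$households <- d2$households[d2$households$cluster_id == 1L, ]
  d2$clusters <- d2$clusters[1, ]
  expect_error(spatord(data = d2, spatial = FALSE), "2 clusters")
})
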