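## S3 methods for fitted "spatord" models.

#' @export
print.spatord <- function(x, ...) {
  cat("Spatial cumulative-logit ordinal model (Laplace-approximated ML)\n")
  cat("Call: "); print(x$call)
  cat(sprintf("%d households, %d clusters, %d categories\n",
              length(x$y), max(x$cluster), x$K))
  cat("Coefficients:\n")
  print(round(x$params$beta, 4))
  cat("Thresholds:", round(x$params$thresholds, 4), "\n")
  if (x$cluster_re) cat("Cluster SD:", round(x$params$sigma_b, 4), "\n")
  if (x$spatial)
    cat("Spatial range:", round(x$params$range, 4),
        " spatial SD:", round(x$params$sigma_u, 4), "\n")
  cat("Marginal NLL:", round(x$convergence$marginal_nll, 3),
      if (x$convergence$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
coef.spatord <- function(object, ...) object$params$beta

#' @export
vcov.spatord <- function(object, ...) object$param_cov

#' @export
logLik.spatord <- function(object, ...) {
  structure(-object$convergence$marginal_nll,
            df = length(object$par), class = "logLik")
}

#' Summary of a fitted spatial ordinal model
#'
#' Wald tests for the fixed effects, delta-method standard errors for the
#' thresholds, and 95% intervals for the variance parameters
#' (log-scale Wald intervals, exponentiated).
#'
#' @param object A fitted `spatord` model.
#' @param ... Unused.
#' @export
summary.spatord <- function(object, ...) {
  p <- length(object$params$beta)
  se <- sqrt(pmax(diag(object$param_cov), 0))
  beta <- object$params$beta
  ct <- cbind(Estimate = beta, `Std. Error` = se[seq_len(p)],
              `z value` = beta / se[seq_len(p)],
              `Pr(>|z|)` = 2 * stats::pnorm(-abs(beta / se[seq_len(p)])))
  rownames(ct) <- object$design

  # thresholds: theta_k = theta1 + sum_{j<k} exp(log_delta_j)
  K <- object$K
  th <- object$params$thresholds
  idx_t <- p + seq_len(K - 1L)
  th_se <- vapply(seq_len(K - 1L), function(k) {
    gvec <- numeric(length(object$par))
    gvec[p + 1] <- 1
    if (k > 1) gvec[p + 1 + seq_len(k - 1)] <- exp(object$params$log_deltas[seq_len(k - 1)])
    sqrt(max(0, drop(t(gvec) %*% object$param_cov %*% gvec)))
  }, numeric(1))
  tt <- cbind(Estimate = th, `Std. Error` = th_se)
  rownames(tt) <- paste0("theta", seq_len(K - 1L))

  vc <- NULL
  nm <- names(object$par)
  ci <- function(name, est) {
    s <- unname(se[match(name, nm)])
    est <- unname(est)
    c(Estimate = est, lower95 = est * exp(-1.96 * s),
      upper95 = est * exp(1.96 * s))
  }
  if (object$cluster_re)
    vc <- rbind(vc, sigma_b = ci("log_sigma_b", object$params$sigma_b))
  if (object$spatial) {
    vc <- rbind(vc, range = ci("log_range", object$params$range))
    vc <- rbind(vc, sigma_u = ci("log_sigma_u", object$params$sigma_u))
  }
  out <- list(call = object$call, coefficients = ct, thresholds = tt,
              variance_components = vc, convergence = object$convergence,
              K = K, n = length(object$y), n_clusters = max(object$cluster))
  class(out) <- "summary.spatord"
  out
}

#' @export
print.summary.spatord <- function(x, ...) {
  cat("Spatial cumulative-logit ordinal model\n")
  cat("Call: "); print(x$call)
  cat(sprintf("%d households, %d clusters, %d categories\n",
              x$n, x$n_clusters, x$K))
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nThresholds:\n"); print(round(x$thresholds, 4))
  if (!is.null(x$variance_components)) {
    cat("\nVariance components (95% log-scale Wald intervals):\n")
    print(round(x$variance_components, 4))
  }
  cat("\nMarginal NLL:", round(x$convergence$marginal_nll, 3),
      " outer gradient norm:", format(x$convergence$gradient_norm, digits = 3),
      "\n")
  invisible(x)
}

## latent mean at the training rows, random effects at their mode
fitted_z <- function(object) {
  z <- drop(object$X %*% object$params$beta)
  if (object$cluster_re) z <- z + object$re_mode$b[object$cluster]
  if (object$spatial)
    z <- z + drop(object$A %*% object$re_mode$w)[object$cluster]
  z
}

#' @export
fitted.spatord <- function(object, ...) {
  class_probabilities(fitted_z(object), object$params$thresholds)
}

#' Predictions from a fitted spatial ordinal model
#'
#' For a data.frame `newdata` (with the model's covariate columns and,
#' when the model has a spatial field, `lon`/`lat`), returns per-row class
#' probabilities at the plug-in estimates: the spatial field contributes its
#' conditional mode interpolated to the new locations, the cluster effect is
#' set to its mean (0) since new locations belong to no sampled cluster.
#' With `se.fit = TRUE`, delta-method standard errors of each class
#' probability are returned: `Var(z*) = x*' Cov(beta) x* + a*' Cov(w|data)
#' a*` (fixed-effect and conditional-field uncertainty; thresholds treated
#' as fixed) and `SE(p_k) = |dp_k/dz| sd(z*)`.
#'
#' For a `prediction_grid`, use [predict_grid()], which this method
#' dispatches to.
#'
#' @param object Fitted `spatord` model.
#' @param newdata Data frame or `prediction_grid`; default the training data.
#' @param type `"probs"` (default), `"class"` (argmax category) or `"link"`
#'   (latent mean `z`).
#' @param se.fit Return delta-method SEs of the class probabilities?
#' @param include_spatial_uncertainty,include_fixed_uncertainty Toggle the
#'   two variance components of `Var(z*)`.
#' @param ... Unused.
#' @export
predict.spatord <- function(object, newdata = NULL,
                            type = c("probs", "class", "link"),
                            se.fit = FALSE,
                            include_spatial_uncertainty = TRUE,
                            include_fixed_uncertainty = TRUE, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "prediction_grid"))
    return(predict_grid(object, newdata, se = se.fit,
                        include_spatial_uncertainty = include_spatial_uncertainty,
                        include_fixed_uncertainty = include_fixed_uncertainty))
  if (is.null(newdata)) {
    z <- fitted_z(object)
    X <- object$X
    A <- if (object$spatial) object$A[object$cluster, , drop = FALSE]
  } else {
    X <- as.matrix(as.data.frame(newdata)[, object$design, drop = FALSE])
    z <- drop(X %*% object$params$beta)
    A <- NULL
    if (object$spatial) {
      if (is.null(newdata$lon))
        stop("newdata needs lon/lat for a spatial model", call. = FALSE)
      A <- projection_matrix(object$mesh, cbind(newdata$lon, newdata$lat))
      z <- z + drop(A %*% object$re_mode$w)
    }
  }
  if (type == "link") return(z)
  probs <- class_probabilities(z, object$params$thresholds)
  if (type == "class") return(max.col(probs, ties.method = "first") - 1L)
  if (!se.fit) return(probs)
  sd_z <- sqrt(latent_variance(object, X, A,
                               include_fixed_uncertainty,
                               include_spatial_uncertainty))
  se <- abs(class_prob_dz(z, object$params$thresholds)) * sd_z
  list(fit = probs, se.fit = se, sd_link = sd_z)
}

## Var(z*) per row: fixed-effect part x' Cov(beta) x plus conditional
## spatial part a' Cov(w | data) a obtained by sparse solves against the
## joint (b, w) Hessian at the mode. beta-w cross-covariance is omitted
## (documented approximation).
latent_variance <- function(object, X, A, fixed = TRUE, spatial = TRUE) {
  q <- nrow(X)
  v <- numeric(q)
  if (fixed) {
    p <- length(object$params$beta)
    covb <- object$param_cov[seq_len(p), seq_len(p), drop = FALSE]
    v <- v + rowSums((X %*% covb) * X)
  }
  if (spatial && object$spatial && !is.null(A)) {
    H <- object$conditional_hessian
    nc <- if (object$cluster_re) max(object$cluster) else 0L
    m <- nrow(object$mesh$nodes)
    S <- Matrix::t(cbind(Matrix::Matrix(0, q, nc, sparse = TRUE), A))
    ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
    HS <- Matrix::solve(ch, S, system = "A")
    v <- v + Matrix::colSums(S * HS)
  }
  pmax(v, 0)
}

#' Simulate replicate outcome vectors from a fitted model
#'
#' Draws replicate category vectors at the training design, propagating
#' random-effect uncertainty by sampling `(b, w)` from the Laplace Gaussian
#' approximation `N(mode, H^-1)` (or holding them at the mode with
#' `re_draw = FALSE`), then sampling categories from the cumulative-logit
#' probabilities. This is the generator behind the posterior predictive
#' check.
#'
#' @param object Fitted `spatord` model.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param re_draw Sample random effects from their conditional Gaussian
#'   (default) instead of fixing them at the mode.
#' @param ... Unused.
#' @return `n x nsim` integer matrix of category draws.
#' @export
simulate.spatord <- function(object, nsim = 1, seed = NULL, re_draw = TRUE,
                             ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(object$y)
  nc <- if (object$cluster_re) max(object$cluster) else 0L
  m <- if (object$spatial) nrow(object$mesh$nodes) else 0L
  n_re <- nc + m
  mode <- c(if (object$cluster_re) object$re_mode$b,
            if (object$spatial) object$re_mode$w)
  ch <- if (re_draw && n_re > 0)
    Matrix::Cholesky(object$conditional_hessian, LDL = FALSE, perm = TRUE)
  out <- matrix(0L, n, nsim)
  eta <- drop(object$X %*% object$params$beta)
  for (s in seq_len(nsim)) {
    v <- mode
    if (re_draw && n_re > 0) {
      zdraw <- stats::rnorm(n_re)
      y1 <- Matrix::solve(ch, zdraw, system = "Lt")
      v <- mode + drop(as.matrix(Matrix::solve(ch, y1, system = "Pt")))
    }
    z <- eta
    if (object$cluster_re) z <- z + v[seq_len(nc)][object$cluster]
    if (object$spatial)
      z <- z + drop(object$A %*% v[nc + seq_len(m)])[object$cluster]
    probs <- class_probabilities(z, object$params$thresholds)
    cum <- row_cumsum(probs); cum[, object$K] <- 1
    out[, s] <- max.col(stats::runif(n) < cum, ties.method = "first") - 1L
  }
  out
}

#' Randomized quantile residuals of a fitted model
#'
#' Dunn-Smyth residuals computed from the fitted class probabilities
#' (random effects at their conditional mode); approximately standard normal
#' under a correctly specified model.
#'
#' @param object Fitted `spatord` model.
#' @param type Only `"dunn-smyth"`.
#' @param seed Integer seed for the randomization.
#' @param ... Unused.
#' @export
residuals.spatord <- function(object, type = "dunn-smyth", seed = NULL, ...) {
  type <- match.arg(type)
  dunn_smyth_residuals(fitted(object), object$y, seed = seed)
}

#' Diagnostic plots for a fitted spatial ordinal model
#'
#' Two panels: a histogram of Dunn-Smyth residuals against the standard
#' normal density, and per-class calibration curves of fitted probability
#' versus observed frequency.
#'
#' @param x Fitted `spatord` model.
#' @param seed Seed for the residual randomization.
#' @param n_bins Calibration bins.
#' @param ... Passed to `hist`.
#' @export
plot.spatord <- function(x, seed = 1L, n_bins = 10, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  r <- residuals(x, seed = seed)
  graphics::hist(r, breaks = 40, freq = FALSE, main = "Dunn-Smyth residuals",
                 xlab = "residual", ...)
  graphics::curve(stats::dnorm(x), add = TRUE, col = "red", lwd = 2)
  cal <- calibration_curve(fitted(x), x$y, n_bins = n_bins)
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "mean predicted probability",
                 ylab = "observed frequency", main = "Calibration")
  for (k in seq_len(x$K)) {
    ck <- cal[cal$class == k - 1L & !cal$empty, ]
    graphics::lines(ck$mean_predicted, ck$observed_frequency,
                    type = "b", col = k, pch = 16)
  }
  graphics::legend("topleft", legend = paste("class", seq_len(x$K) - 1L),
                   col = seq_len(x$K), pch = 16, bty = "n")
  invisible(x)
}
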