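## Model validation suite: Dunn-Smyth randomized quantile residuals,
## calibration curves, posterior predictive checks, per-class
## confusion-matrix metrics and exact Shapley attributions of the linear
## predictor.

#' Dunn-Smyth randomized quantile residuals for ordinal outcomes
#'
#' For observation i with cumulative category probabilities `F_i`, draws
#' `u_i ~ Uniform(F_i(y_i - 1), F_i(y_i))` (with `F(-1) = 0`) and returns
#' `qnorm(u_i)`; exactly standard normal when the probabilities are the true
#' ones. `u` is clipped to `[1e-12, 1 - 1e-12]` before the normal quantile.
#'
#' @param probs `n x K` matrix of class probabilities (rows sum to 1).
#' @param y Integer categories in `0..K-1`.
#' @param seed Integer seed; residuals are deterministic given it.
#' @return Numeric vector of n residuals.
#' @export
dunn_smyth_residuals <- function(probs, y, seed = NULL) {
  probs <- as.matrix(probs)
  n <- nrow(probs); K <- ncol(probs)
  if (length(y) != n) stop("length(y) != nrow(probs)", call. = FALSE)
  if (any(abs(rowSums(probs) - 1) > 1e-6) || any(probs < -1e-12))
    stop("probs rows must be valid probability vectors summing to 1",
         call. = FALSE)
  if (any(y < 0L | y >= K)) stop("y out of range", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  Fm <- cbind(0, row_cumsum(probs))
  i <- seq_len(n)
  lo <- Fm[cbind(i, y + 1L)]
  hi <- Fm[cbind(i, y + 2L)]
  u <- stats::runif(n, lo, hi)
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' Per-class calibration table
#'
#' Bins each class's predicted probability into `n_bins` equal-width bins on
#' `[0, 1]` and tabulates the mean predicted probability against the observed
#' frequency of that class. Empty bins are kept and flagged, never silently
#' dropped.
#'
#' @inheritParams dunn_smyth_residuals
#' @param n_bins Number of equal-width bins (`>= 2`, default 10).
#' @return data.frame with columns `class` (0-based), `bin`, `midpoint`,
#'   `mean_predicted`, `observed_frequency`, `count`, `empty`.
#' @export
calibration_curve <- function(probs, y, n_bins = 10) {
  stopifnot(n_bins >= 2)
  probs <- as.matrix(probs)
  K <- ncol(probs)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  mid <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  out <- vector("list", K)
  for (k in seq_len(K)) {
    p <- probs[, k]
    bin <- findInterval(p, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    cnt <- tabulate(bin, nbins = n_bins)
    mp <- of <- rep(NA_real_, n_bins)
    nz <- which(cnt > 0)
    mp[nz] <- vapply(nz, function(bn) mean(p[bin == bn]), numeric(1))
    of[nz] <- vapply(nz, function(bn) mean(y[bin == bn] == k - 1L), numeric(1))
    out[[k]] <- data.frame(class = k - 1L, bin = seq_len(n_bins),
                           midpoint = mid, mean_predicted = mp,
                           observed_frequency = of, count = cnt,
                           empty = cnt == 0L)
  }
  do.call(rbind, out)
}

#' Posterior predictive check of outcome category frequencies
#'
#' Draws `n_rep` replicate outcome vectors from the fitted model (random
#' effects sampled from the Laplace Gaussian approximation `N(mode, H^-1)`
#' by default) and compares observed category frequencies with the mean
#' replicate frequencies.
#'
#' @param model Fitted `spatord` model.
#' @param n_rep Number of replicate datasets (`>= 1`).
#' @param seed Integer seed.
#' @param re_draw Propagate random-effect uncertainty (default) or fix the
#'   random effects at their mode.
#' @return List with `table` (data.frame: category, observed, replicate_mean)
#'   and `max_abs_diff`.
#' @export
posterior_predictive_check <- function(model, n_rep = 100, seed = 1L,
                                       re_draw = TRUE) {
  stopifnot(inherits(model, "spatord"), n_rep >= 1)
  reps <- simulate(model, nsim = n_rep, seed = seed, re_draw = re_draw)
  n <- length(model$y)
  obs <- tabulate(model$y + 1L, nbins = model$K) / n
  rep_freq <- vapply(seq_len(n_rep),
                     function(s) tabulate(reps[, s] + 1L, nbins = model$K) / n,
                     numeric(model$K))
  rep_mean <- rowMeans(rep_freq)
  list(table = data.frame(category = seq_len(model$K) - 1L, observed = obs,
                          replicate_mean = rep_mean),
       max_abs_diff = max(abs(obs - rep_mean)))
}

#' One-vs-rest classification metrics per ordinal class
#'
#' Predicted class is the probability argmax (ties to the lowest category).
#' Per class: AUC from the rank (Mann-Whitney) statistic on that class's
#' probability with midrank tie handling; precision, recall and F1 from the
#' one-vs-rest confusion matrix; accuracy is one-vs-rest accuracy; support
#' the class count. Classes without both a positive and a negative are
#' flagged undefined (`NA` metrics).
#'
#' @inheritParams dunn_smyth_residuals
#' @return data.frame with columns `class`, `auc`, `precision`, `recall`,
#'   `f1`, `accuracy`, `support`, `undefined`.
#' @export
classification_metrics <- function(probs, y) {
  probs <- as.matrix(probs)
  n <- nrow(probs); K <- ncol(probs)
  stopifnot(n >= 2, length(y) == n)
  pred <- max.col(probs, ties.method = "first") - 1L
  out <- data.frame(class = seq_len(K) - 1L, auc = NA_real_,
                    precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                    accuracy = NA_real_, support = tabulate(y + 1L, K),
                    undefined = FALSE)
  for (k in seq_len(K)) {
    pos <- y == k - 1L
    n1 <- sum(pos); n0 <- n - n1
    if (n1 == 0L || n0 == 0L) {
      out$undefined[k] <- TRUE
      next
    }
    r <- rank(probs[, k])  # midranks
    out$auc[k] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    tp <- sum(pred == k - 1L & pos); fp <- sum(pred == k - 1L & !pos)
    fn <- sum(pred != k - 1L & pos); tn <- n - tp - fp - fn
    out$precision[k] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    out$recall[k] <- tp / (tp + fn)
    pr <- out$precision[k]; rc <- out$recall[k]
    out$f1[k] <- if (!is.na(pr) && pr + rc > 0) 2 * pr * rc / (pr + rc) else NA_real_
    out$accuracy[k] <- (tp + tn) / n
  }
  out
}

#' Exact Shapley attributions of the linear predictor
#'
#' For the fixed-effect linear predictor `eta = X beta` the Shapley
#' decomposition under feature independence is exact and closed-form:
#' `phi_ij = beta_j * (x_ij - mean_j)`, so each row sums to
#' `eta_i - mean(eta)`. Attributions cover the covariate effects only; the
#' spatial field and cluster effects are not features and are excluded.
#'
#' @param model Fitted `spatord` model, or a numeric coefficient vector.
#' @param X `n x p` covariate matrix (default: the model's training matrix).
#' @param background_means Per-feature reference means (default: training
#'   column means).
#' @return List with `attributions` (`n x p` matrix) and `ranking`
#'   (data.frame: feature, mean_abs_attribution, ordered decreasing).
#' @export
shap_linear <- function(model, X = NULL, background_means = NULL) {
  beta <- if (inherits(model, "spatord")) model$params$beta else as.numeric(model)
  if (is.null(X)) {
    stopifnot(inherits(model, "spatord"))
    X <- model$X
  }
  X <- as.matrix(X)
  if (ncol(X) != length(beta))
    stop("ncol(X) != length(beta)", call. = FALSE)
  if (is.null(background_means)) background_means <- colMeans(X)
  if (length(background_means) != length(beta))
    stop("background_means length mismatch", call. = FALSE)
  phi <- sweep(X, 2, background_means) * rep(beta, each = nrow(X))
  colnames(phi) <- if (!is.null(colnames(X))) colnames(X)
    else paste0("x", seq_along(beta))
  rk <- data.frame(feature = colnames(phi),
                   mean_abs_attribution = colMeans(abs(phi)))
  rk <- rk[order(-rk$mean_abs_attribution), ]
  rownames(rk) <- NULL
  list(attributions = phi, ranking = rk)
}

#' Full diagnostics report for a fitted model
#'
#' Bundles the validation suite: calibration table, Dunn-Smyth residuals
#' with summary statistics (mean, SD, skewness, Kolmogorov-Smirnov statistic
#' against N(0,1)), posterior predictive check, per-class classification
#' metrics and Shapley attributions of the linear predictor.
#'
#' @param model Fitted `spatord` model.
#' @param n_bins Calibration bins.
#' @param n_rep PPC replicates.
#' @param seed Integer seed for the randomized components.
#' @return Object of class `spatord_diagnostics`.
#' @export
diagnose <- function(model, n_bins = 10, n_rep = 50, seed = 1L) {
  stopifnot(inherits(model, "spatord"))
  probs <- fitted(model)
  r <- dunn_smyth_residuals(probs, model$y, seed = seed)
  ks <- suppressWarnings(stats::ks.test(r, "pnorm"))
  m <- mean(r); s <- stats::sd(r)
  res_summary <- c(mean = m, sd = s,
                   skewness = mean(((r - m) / s)^3),
                   ks_statistic = unname(ks$statistic),
                   ks_pvalue = ks$p.value)
  structure(list(
    calibration = calibration_curve(probs, model$y, n_bins),
    residuals = r, residual_summary = res_summary,
    ppc = posterior_predictive_check(model, n_rep = n_rep, seed = seed + 1L),
    metrics = classification_metrics(probs, model$y),
    shap = shap_linear(model)),
    class = "spatord_diagnostics")
}

#' @export
print.spatord_diagnostics <- function(x, ...) {
  cat("spatord diagnostics\n")
  cat("Dunn-Smyth residuals: mean", round(x$residual_summary["mean"], 4),
      " sd", round(x$residual_summary["sd"], 4),
      " KS p", format(x$residual_summary["ks_pvalue"], digits = 3), "\n")
  cat("PPC max |obs - rep| frequency difference:",
      round(x$ppc$max_abs_diff, 4), "\n")
  cat("Per-class metrics:\n")
  print(round_df(x$metrics, 3))
  cat("Top features by mean |Shapley|:\n")
  print(utils::head(x$shap$ranking, 5))
  invisible(x)
}

round_df <- function(d, k) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, k)
  d
}

#' Write a diagnostics report to CSV tables and a JSON summary
#'
#' @param report A `spatord_diagnostics`.
#' @param out_dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_diagnostics <- function(report, out_dir) {
  stopifnot(inherits(report, "spatord_diagnostics"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    calibration = file.path(out_dir, "calibration.csv"),
    metrics = file.path(out_dir, "metrics.csv"),
    ppc = file.path(out_dir, "ppc.csv"),
    residuals = file.path(out_dir, "residuals.csv"),
    shap = file.path(out_dir, "shap_ranking.csv"),
    summary = file.path(out_dir, "summary.json"))
  utils::write.csv(report$calibration, paths["calibration"], row.names = FALSE)
  utils::write.csv(report$metrics, paths["metrics"], row.names = FALSE)
  utils::write.csv(report$ppc$table, paths["ppc"], row.names = FALSE)
  utils::write.csv(data.frame(residual = report$residuals),
                   paths["residuals"], row.names = FALSE)
  utils::write.csv(report$shap$ranking, paths["shap"], row.names = FALSE)
  summ <- c(as.list(report$residual_summary),
            list(ppc_max_abs_diff = report$ppc$max_abs_diff))
  writeLines(simple_json(summ), paths["summary"])
  invisible(paths)
}

## tiny flat-list JSON emitter (numbers and strings only)
simple_json <- function(x) {
  items <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    val <- if (is.numeric(v)) format(v, digits = 15) else
      paste0('"', v, '"')
    paste0('"', nm, '": ', val)
  }, character(1))
  paste0("{", paste(items, collapse = ", "), "}")
}
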