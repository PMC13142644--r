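#' Cumulative-logit thresholds from unconstrained parameters
#'
#' Maps the unconstrained parameterisation (first threshold plus log
#' increments) to a strictly increasing threshold vector. With `K` outcome
#' categories there are `K - 1` thresholds: `theta[1] = theta1` and
#' `theta[k] = theta[k-1] + exp(log_deltas[k-1])`, so monotonicity holds by
#' construction and the outer optimiser can work on an unconstrained scale.
#'
#' @param theta1 First (smallest) threshold, a finite scalar.
#' @param log_deltas Numeric vector of length `K - 2` of log increments
#'   between consecutive thresholds (length 0 for a binary outcome).
#' @return Numeric vector of `K - 1` strictly increasing thresholds.
#' @examples
#' thresholds_from_raw(-1, 0)       # c(-1, 0)
#' thresholds_from_raw(0, numeric(0))  # single threshold, K = 2
#' @export
thresholds_from_raw <- function(theta1, log_deltas = numeric(0)) {
  stopifnot(is.numeric(theta1), length(theta1) == 1L, is.finite(theta1),
            is.numeric(log_deltas), all(is.finite(log_deltas)))
  theta1 + c(0, cumsum(exp(log_deltas)))
}

check_thresholds <- function(thresholds) {
  if (!is.numeric(thresholds) || length(thresholds) < 1L ||
      any(!is.finite(thresholds)))
    stop("thresholds must be a finite numeric vector", call. = FALSE)
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  invisible(thresholds)
}

#' Ordinal category probabilities under the cumulative logit model
#'
#' Computes `P(y = k) = logit^-1(theta_k+1 - z) - logit^-1(theta_k - z)` for
#' categories `k = 0, ..., K-1`, with the conventions `theta_0 = -Inf` and
#' `theta_K = +Inf`. Category 0 is the reference (least improved) level.
#'
#' @param z Numeric vector of latent means.
#' @param thresholds Strictly increasing numeric vector of length `K - 1`.
#' @return A `length(z) x K` matrix of probabilities; rows sum to 1.
#' @examples
#' class_probabilities(0, c(-1, 1))  # 0.2689, 0.4621, 0.2689
#' @export
class_probabilities <- function(z, thresholds) {
  check_thresholds(thresholds)
  K <- length(thresholds) + 1L
  cum <- stats::plogis(outer(-z, thresholds, `+`))  # sigma(theta_k - z)
  p <- cbind(cum, 1) - cbind(0, cum)
  dimnames(p) <- list(NULL, paste0("p", seq_len(K) - 1L))
  p
}

## Stable per-observation ordinal log-likelihood and z-derivatives.
## For category y with bounds a = theta_lo - z, b = theta_up - z:
##   p = sigma(b) - sigma(a) = sigma(b) * sigma(-a) * (1 - exp(a - b))
## which is evaluated in logs to avoid cancellation for |theta - z| large.
## Returns logp, g = d(-logp)/dz and h = d2(-logp)/dz2 (h >= 0 by convexity).
ordinal_terms <- function(z, y, thresholds, hess_floor = 1e-10) {
  K <- length(thresholds) + 1L
  if (any(y < 0L | y >= K)) stop("y out of range 0..K-1", call. = FALSE)
  n <- length(z)
  th <- c(-Inf, thresholds, Inf)
  a <- th[y + 1L] - z        # lower bound, -Inf for y = 0
  b <- th[y + 2L] - z        # upper bound, +Inf for y = K-1
  logp <- g <- h <- numeric(n)

  lo <- is.infinite(a)   # lowest category: p = sigma(b)
  hi <- is.infinite(b)   # highest category: p = sigma(-a)
  mid <- !(lo | hi)

  if (any(lo)) {
    bb <- b[lo]
    lsb <- stats::plogis(bb, log.p = TRUE)
    lsnb <- stats::plogis(-bb, log.p = TRUE)
    logp[lo] <- lsb
    # -d/dz log sigma(b) = sigma(-b), with db/dz = -1
    g[lo] <- exp(lsnb)
    h[lo] <- exp(lsb + lsnb)
  }
  if (any(hi)) {
    aa <- a[hi]
    lsa <- stats::plogis(aa, log.p = TRUE)
    lsna <- stats::plogis(-aa, log.p = TRUE)
    logp[hi] <- lsna
    g[hi] <- -exp(lsa)
    h[hi] <- exp(lsa + lsna)
  }
  if (any(mid)) {
    aa <- a[mid]; bb <- b[mid]
    lsb <- stats::plogis(bb, log.p = TRUE)
    lsnb <- stats::plogis(-bb, log.p = TRUE)
    lsa <- stats::plogis(aa, log.p = TRUE)
    lsna <- stats::plogis(-aa, log.p = TRUE)
    lp <- lsb + lsna + log1p(-exp(aa - bb))
    logp[mid] <- lp
    gm <- hm <- numeric(length(aa))
    # far outside the (lower, upper) band the NLL is asymptotically linear
    # in z with slope +-1; switch to that limit before exp(-logp) overflows
    far_up <- bb < -35          # z far above the upper threshold
    far_dn <- aa > 35           # z far below the lower threshold
    ok <- !(far_up | far_dn)
    db <- exp(lsb + lsnb); da <- exp(lsa + lsna)          # sigma'
    d2b <- db * (1 - 2 * exp(lsb)); d2a <- da * (1 - 2 * exp(lsa))  # sigma''
    ip <- exp(-lp[ok])
    gm[ok] <- (db[ok] - da[ok]) * ip
    hm[ok] <- gm[ok]^2 - (d2b[ok] - d2a[ok]) * ip
    gm[far_up] <- 1; gm[far_dn] <- -1
    g[mid] <- gm
    h[mid] <- hm
  }
  if (any(!is.finite(logp)))
    stop("non-finite ordinal log-likelihood term", call. = FALSE)
  list(logp = logp, g = g, h = pmax(h, hess_floor))
}

#' Negative log-likelihood of ordinal observations
#'
#' Numerically stable `-log P(y | z)` under the cumulative logit model,
#' formulated as a log-difference of sigmoids so that thresholds tens of
#' units away from `z` do not underflow or cancel catastrophically.
#'
#' @param y Integer vector of observed categories in `0..K-1`.
#' @param z Numeric vector of latent means (recycled against `y`).
#' @param thresholds Strictly increasing numeric vector, length `K - 1`.
#' @return Numeric vector of per-observation negative log-likelihoods.
#' @examples
#' ordinal_nll(0, 0, 0)  # log 2
#' @export
ordinal_nll <- function(y, z, thresholds) {
  check_thresholds(thresholds)
  n <- max(length(y), length(z))
  y <- as.integer(rep_len(y, n)); z <- rep_len(z, n)
  -ordinal_terms(z, y, thresholds)$logp
}

## d p_k / dz for every category k at latent mean z:
## -sigma'(theta_k - z) + sigma'(theta_{k-1} - z); used by the delta method.
class_prob_dz <- function(z, thresholds) {
  dsig <- function(x) stats::dlogis(x)
  d <- dsig(outer(-z, thresholds, `+`))
  cbind(0, d) - cbind(d, 0)  # dp_k/dz = sigma'(theta_lo - z) - sigma'(theta_up - z)
}

## fast row-wise cumulative sum for small K (avoids t(apply(...)))
row_cumsum <- function(P) {
  out <- P
  for (k in seq_len(ncol(P))[-1]) out[, k] <- out[, k - 1] + P[, k]
  out
}
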