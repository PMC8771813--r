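#' Local two-scale dimension estimates
#'
#' The local estimate at a point compares the distances to the k-th and 2k-th
#' nearest neighbor:
#' \deqn{\delta_k(x_i) = \ln 2 / \ln(R_{2k}^i / R_k^i).}
#' Degenerate radii are handled explicitly: `r_k == r_2k > 0` (exact ties
#' across the two scales) gives `delta = Inf`; `r_k == 0 < r_2k` (at least
#' k+1 coincident points) would give a meaningless `delta = 0`, so such points
#' are also mapped to `Inf` and counted, keeping the median aggregate robust.
#' If some `r_2k == 0` (at least 2k+1 coincident points) the cloud is rejected.
#'
#' @param radii a [knn_radii()] result.
#' @return An object of class `local_fsa`: list with `k`, `delta` (length-n,
#'   positive, possibly `Inf`) and `n_degenerate` (points with `r_k == 0`).
#' @export
local_fsa <- function(radii) {
  stopifnot(inherits(radii, "neighbor_radii"))
  r_k <- radii$r_k; r_2k <- radii$r_2k
  if (any(r_2k == 0))
    stop("degenerate cloud: some point has 2k coincident neighbors (r_2k = 0)")
  delta <- log(2) / log(r_2k / r_k)
  zero <- r_k == 0
  tie <- !zero & r_k == r_2k
  delta[zero | tie] <- Inf
  n_deg <- sum(zero)
  if (n_deg > 0)
    warning(sprintf("%d point(s) with r_k = 0 flagged degenerate (delta set to Inf)",
                    n_deg))
  structure(list(k = radii$k, delta = delta, n_degenerate = n_deg),
            class = "local_fsa")
}

#' @export
print.local_fsa <- function(x, ...) {
  cat(sprintf("local FSA estimates: n = %d, k = %d, finite = %d\n",
              length(x$delta), x$k, sum(is.finite(x$delta))))
  invisible(x)
}

as_delta <- function(local) {
  if (inherits(local, "local_fsa")) local$delta else as.numeric(local)
}

local_k <- function(local) {
  if (inherits(local, "local_fsa")) local$k else NA_integer_
}

global_estimate <- function(value, statistic, k, n_effective) {
  structure(list(value = value, statistic = statistic, k = k,
                 n_effective = n_effective),
            class = "global_estimate")
}

#' @export
print.global_estimate <- function(x, ...) {
  cat(sprintf("global dimension estimate (%s, k = %d): %.4f  [n_eff = %d]\n",
              x$statistic, x$k, x$value, x$n_effective))
  invisible(x)
}

#' Global aggregates of local estimates
#'
#' `fsa_mean()` is the arithmetic mean of the local estimates (the original
#' aggregate; infinite locals propagate, and its expectation diverges at
#' k = 1). `fsa_median()` is the sample median (mFSA), asymptotically unbiased
#' for any k under locally uniform density; for even counts the midpoint of
#' the two central order statistics is used, so a median between a finite and
#' an infinite local is infinite only when at least half the locals are.
#'
#' @param local a [local_fsa()] result or a numeric vector of local estimates.
#' @param k neighborhood size, needed only when `local` is a bare vector.
#' @return A `global_estimate` object (value, statistic, k, n_effective).
#' @export
fsa_mean <- function(local, k = NULL) {
  delta <- as_delta(local)
  if (length(delta) < 1L) stop("no local estimates")
  k <- k %||% local_k(local)
  global_estimate(mean(delta), "mean", k, sum(is.finite(delta)))
}

#' @rdname fsa_mean
#' @export
fsa_median <- function(local, k = NULL) {
  delta <- as_delta(local)
  if (length(delta) < 1L) stop("no local estimates")
  k <- k %||% local_k(local)
  global_estimate(median(delta), "median", k, sum(is.finite(delta)))
}

# score function of the log likelihood in D (zero at the ML estimate)
ml_score <- function(D, delta, k) {
  length(delta) / D - log(2) * k * sum(1 / delta) +
    log(2) * (k - 1) * sum(1 / (delta * (2^(D / delta) - 1)))
}

#' Maximum-likelihood global dimension
#'
#' Treats the local estimates as i.i.d. draws from their exact law under
#' locally uniform density and maximizes the likelihood in D. For k = 1 the
#' score has the closed-form root
#' \eqn{D = n / (\ln 2 \sum_i 1/\delta_i) = n / \sum_i \ln(R_2^i/R_1^i)},
#' which coincides with the Levina-Bickel k = 1 formula. For k > 1 the score
#' equation is transcendental and the unique positive root is found
#' numerically: the bracket starts at \eqn{[10^{-6}, u]} and the upper end is
#' doubled until a sign change, then bisection/interpolation refines the root
#' to |score| < 1e-10.
#'
#' @inheritParams fsa_mean
#' @param upper initial upper bracket for the root search (default ten times
#'   the median local estimate).
#' @return A `global_estimate` with `statistic = "ml"`.
#' @export
ml_dimension <- function(local, k = NULL, upper = NULL) {
  delta <- as_delta(local)
  k <- k %||% local_k(local)
  if (is.na(k)) stop("k must be supplied with a bare vector of local estimates")
  if (length(delta) < 1L) stop("no local estimates")
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop("maximum-likelihood estimation requires finite positive local estimates")
  n <- length(delta)
  if (k == 1L) {
    D <- n / (log(2) * sum(1 / delta))
    return(global_estimate(D, "ml", k, n))
  }
  lo <- 1e-6
  up <- upper %||% max(10 * median(delta), 1)
  f_lo <- ml_score(lo, delta, k)
  f_up <- ml_score(up, delta, k)
  tries <- 0L
  while (f_lo * f_up > 0 && tries < 60L) {
    up <- up * 2
    f_up <- ml_score(up, delta, k)
    tries <- tries + 1L
  }
  if (f_lo * f_up > 0)
    stop("could not bracket the likelihood root after bracket expansion")
  root <- uniroot(ml_score, c(lo, up), delta = delta, k = k,
                  tol = .Machine$double.eps^0.6)$root
  # polish with a few Newton-free bisections if the score is not tiny yet
  if (abs(ml_score(root, delta, k)) > 1e-10) {
    root <- uniroot(ml_score, c(max(lo, root * 0.9), root * 1.1),
                    delta = delta, k = k, tol = .Machine$double.eps)$root
  }
  global_estimate(root, "ml", k, n)
}

# Levina-Bickel estimate from an n x k matrix of sorted neighbor distances.
# convention "inverse": invert the global average of inverse local estimates
# (equivalently pool all log-ratios); "mean": average the per-point estimates.
lb_from_dists <- function(d, k, convention = c("inverse", "mean")) {
  convention <- match.arg(convention)
  if (k < 2L) stop("Levina-Bickel needs k >= 2")
  logratio <- log(d[, k] / d[, seq_len(k - 1L), drop = FALSE])
  inv_local <- rowSums(logratio) / (k - 1L)   # 1 / m_k(x_i)
  if (any(!is.finite(inv_local)) || any(inv_local <= 0))
    stop("degenerate neighbor distances in Levina-Bickel estimate")
  if (convention == "inverse") 1 / mean(inv_local) else mean(1 / inv_local)
}

#' Levina-Bickel maximum-likelihood baseline
#'
#' The classical kNN maximum-likelihood dimension estimator, included as a
#' comparison baseline. The default `"inverse"` convention inverts the global
#' average of the per-point inverse estimates (equivalent to pooling all
#' log-distance ratios); `"mean"` averages the per-point estimates instead.
#'
#' @inheritParams knn_radii
#' @param convention `"inverse"` (default) or `"mean"`.
#' @return A `global_estimate` with `statistic = "ml"`.
#' @export
levina_bickel <- function(cloud, k, boundary = "hard",
                          convention = c("inverse", "mean")) {
  convention <- match.arg(convention)
  cloud <- as_point_cloud(cloud, boundary)
  k <- as.integer(k)
  if (k < 2L) stop("Levina-Bickel needs k >= 2")
  d <- knn_distances(cloud, k)
  global_estimate(lb_from_dists(d, k, convention), "ml", k, nrow(d))
}

#' Fit a global intrinsic-dimension estimate
#'
#' The main fitting front-end. Computes local two-scale estimates at every
#' point for one or more neighborhood sizes `k` and aggregates them with the
#' chosen statistic (median by default, the mFSA estimator). Returns a classed
#' object with `print`, `summary`, `coef` and `plot` methods.
#'
#' @param x a [point_cloud], matrix or data frame (rows = points).
#' @param k neighborhood size(s); a vector gives one estimate per k.
#' @param statistic `"median"` (mFSA), `"mean"` (original FSA) or `"ml"`.
#' @param boundary distance convention when `x` is not already a point cloud.
#' @param correction optional [fsa_correction] model; when supplied the
#'   median estimates are passed through the calibrated bias correction
#'   (see [cmfsa()] for the one-shot interface).
#' @param keep_local keep the matrix of local estimates in the result.
#' @return An object of class `fsa` with components `estimates` (data frame
#'   with columns `k`, `estimate`, `n_effective`), `statistic`, `boundary`,
#'   `n`, `m`, `n_degenerate`, and optionally `local` (an n-by-length(k)
#'   matrix of local estimates).
#' @examples
#' pc <- sample_hypercube(500, 2, boundary = "periodic", seed = 1)
#' fit <- fsa(pc, k = 1:10)
#' coef(fit)          # per-k mFSA estimates, all close to 2
#' summary(fit)
#' @export
fsa <- function(x, k = 1L, statistic = c("median", "mean", "ml"),
                boundary = "hard", correction = NULL, keep_local = TRUE) {
  statistic <- match.arg(statistic)
  cloud <- as_point_cloud(x, boundary)
  k <- sort(unique(as.integer(k)))
  if (any(k < 1L)) stop("k must be positive")
  n <- nrow(cloud$coords)
  if (n <= 2L * max(k))
    stop(sprintf("need n > 2k for every k (n = %d, max k = %d)", n, max(k)))
  d <- knn_distances(cloud, 2L * max(k))
  locals <- matrix(NA_real_, n, length(k))
  est <- data.frame(k = k, estimate = NA_real_, n_effective = NA_integer_)
  n_deg <- 0L
  for (j in seq_along(k)) {
    radii <- structure(list(k = k[j], r_k = d[, k[j]], r_2k = d[, 2L * k[j]]),
                       class = "neighbor_radii")
    loc <- local_fsa(radii)
    n_deg <- max(n_deg, loc$n_degenerate)
    g <- switch(statistic,
                median = fsa_median(loc),
                mean = fsa_mean(loc),
                ml = ml_dimension(loc))
    locals[, j] <- loc$delta
    est$estimate[j] <- g$value
    est$n_effective[j] <- g$n_effective
  }
  if (!is.null(correction)) {
    if (statistic != "median")
      warning("the bias correction is calibrated for the median statistic")
    est$corrected <- apply_correction(est$estimate, correction)
  }
  structure(list(estimates = est, statistic = statistic,
                 boundary = cloud$boundary, n = n, m = ncol(cloud$coords),
                 n_degenerate = n_deg,
                 local = if (keep_local) locals else NULL,
                 call = match.call()),
            class = "fsa")
}

#' @export
print.fsa <- function(x, digits = 4, ...) {
  cat(sprintf("Intrinsic dimension fit (%s statistic, %s boundary)\n",
              x$statistic, x$boundary))
  cat(sprintf("  n = %d points in %d ambient coordinates\n", x$n, x$m))
  print(format(x$estimates, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.fsa <- function(object, ...) {
  col <- if (!is.null(object$estimates$corrected)) "corrected" else "estimate"
  stats::setNames(object$estimates[[col]], paste0("k", object$estimates$k))
}

#' @export
summary.fsa <- function(object, ...) {
  est <- coef(object)
  out <- list(fit = object, mean_over_k = mean(est),
              se = median_se_approx(mean(est), mean(object$estimates$k), object$n))
  class(out) <- "summary.fsa"
  out
}

#' @export
print.summary.fsa <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  mean over k: %.*f   (approximate SE of a single median: %.*f)\n",
              digits, x$mean_over_k, digits, x$se))
  if (x$fit$n_degenerate > 0)
    cat(sprintf("  degenerate points (r_k = 0): %d\n", x$fit$n_degenerate))
  invisible(x)
}

#' @export
plot.fsa <- function(x, true_D = NULL, ...) {
  est <- x$estimates
  plot(est$k, est$estimate, type = "b", xlab = "neighborhood size k",
       ylab = sprintf("%s estimate", x$statistic), ...)
  if (!is.null(est$corrected)) {
    lines(est$k, est$corrected, type = "b", col = 2)
    legend("topright", c("raw", "corrected"), col = 1:2, lty = 1, bty = "n")
  }
  if (!is.null(true_D)) abline(h = true_D, lty = 2, col = "grey40")
  invisible(x)
}

#' Global estimates over a range of neighborhood sizes
#'
#' Convenience wrapper around [fsa()] for a contiguous k-range; also reports
#' the mean of the per-k estimates, the aggregation used when estimates are
#' averaged "over the neighborhoods".
#'
#' @inheritParams fsa
#' @param k_min,k_max neighborhood range (inclusive).
#' @return A list with `estimates` (data frame k, estimate, n_effective) and
#'   `mean_over_k`.
#' @export
estimate_over_k <- function(x, k_min, k_max, statistic = c("median", "mean", "ml"),
                            boundary = "hard") {
  statistic <- match.arg(statistic)
  fit <- fsa(x, k = k_min:k_max, statistic = statistic, boundary = boundary,
             keep_local = FALSE)
  list(estimates = fit$estimates, mean_over_k = mean(fit$estimates$estimate))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
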