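#' Closed-form single-coefficient bias correction fit
#'
#' For the one-parameter correction \eqn{D \approx d e^{\alpha d}} the
#' least-squares solution on pooled calibration pairs has the closed form
#' \deqn{\alpha = \sum_i (\ln E_i) d^{(i)} / \sum_i (d^{(i)})^2,}
#' where \eqn{E_i = D_i / d^{(i)}} is the relative error of the biased
#' estimate \eqn{d^{(i)}} against the true dimension \eqn{D_i}.
#'
#' @param true_D true dimensions, one per calibration estimate (recycled
#'   against `estimate`).
#' @param estimate biased (e.g. mFSA) estimates, positive.
#' @return The scalar coefficient alpha.
#' @export
fit_alpha_closed_form <- function(true_D, estimate) {
  if (length(estimate) < 1L) stop("need at least one calibration estimate")
  if (any(!is.finite(estimate)) || any(estimate <= 0))
    stop("calibration estimates must be positive and finite")
  true_D <- rep_len(true_D, length(estimate))
  lE <- log(true_D / estimate)
  sum(lE * estimate) / sum(estimate^2)
}

# intercept-free multivariate total least squares via SVD:
# minimizes orthogonal distance of rows of [X y] to the subspace.
tls_fit <- function(X, y) {
  s <- svd(cbind(X, y))
  v <- s$v[, ncol(s$v)]
  p <- ncol(X)
  if (abs(v[p + 1]) < 1e-12) stop("degenerate orthogonal-distance fit")
  -v[seq_len(p)] / v[p + 1]
}

correction_design <- function(d, exponents) {
  X <- vapply(exponents, function(l) d^l, numeric(length(d)))
  matrix(X, nrow = length(d),
         dimnames = list(NULL, paste0("d^", exponents)))
}

#' Fit the exponential-polynomial bias-correction model
#'
#' The correction model states that the log relative error of the biased
#' estimate is polynomial in the estimate:
#' \deqn{\ln(D/d) = \sum_l \alpha_l d^l,}
#' equivalently \eqn{D \approx d \exp(\sum_l \alpha_l d^l)}. The exponents
#' `l` may include -1. The fit is linear in the coefficients with no
#' intercept beyond the supplied exponents:
#' \describe{
#'   \item{`ols_all`}{ordinary least squares pooling every
#'     realization-level pair (with exponents `c(1)` this reproduces
#'     [fit_alpha_closed_form()] exactly).}
#'   \item{`odr_means`}{orthogonal distance regression (total least squares)
#'     on the per-true-D means of the log relative error against the
#'     per-true-D mean estimates.}
#' }
#'
#' @inheritParams fit_alpha_closed_form
#' @param exponents integer exponents of the polynomial, e.g. `c(1)` for the
#'   narrow hard-boundary regime or `c(-1, 1, 2, 3)` for wide calibrations.
#' @param method `"ols_all"` or `"odr_means"`.
#' @param n_cal,k_cal,seed calibration metadata stored in the model.
#' @return An object of class `fsa_correction`: exponents, coefficients,
#'   calibration metadata, per-true-D residual statistics of the corrected
#'   log relative error, and the range of calibration estimates.
#' @export
fit_correction <- function(true_D, estimate, exponents = c(1),
                           method = c("ols_all", "odr_means"),
                           n_cal = NA_integer_, k_cal = NA_integer_,
                           seed = NA_integer_) {
  method <- match.arg(method)
  if (any(!is.finite(estimate)) || any(estimate <= 0))
    stop("calibration estimates must be positive and finite")
  true_D <- rep_len(true_D, length(estimate))
  if (length(unique(true_D)) < 2L)
    stop("calibration needs at least two distinct true dimensions")
  exponents <- as.numeric(exponents)
  y <- log(true_D / estimate)
  if (method == "ols_all") {
    X <- correction_design(estimate, exponents)
    fit <- lm.fit(X, y)
    if (fit$rank < ncol(X)) stop("rank-deficient correction design")
    coeffs <- unname(fit$coefficients)
  } else {
    dbar <- tapply(estimate, true_D, mean)
    ybar <- tapply(y, true_D, mean)
    X <- correction_design(as.numeric(dbar), exponents)
    if (qr(X)$rank < ncol(X)) stop("rank-deficient correction design")
    coeffs <- tls_fit(X, as.numeric(ybar))
  }
  model <- structure(
    list(exponents = exponents, coeffs = coeffs,
         n_cal = as.integer(n_cal), k_cal = as.integer(k_cal),
         d_range = range(true_D), fit_method = method,
         est_range = range(estimate), seed = seed,
         residual_stats = NULL, version = "fsadim 0.1.0"),
    class = "fsa_correction")
  corrected <- apply_correction(estimate, model, warn = FALSE)
  e <- log(true_D / corrected)   # residual log relative error after correction
  rs <- data.frame(
    true_D = as.numeric(names(tapply(e, true_D, mean))),
    mean_log_err = as.numeric(tapply(e, true_D, mean)),
    sd_log_err = as.numeric(tapply(e, true_D, sd)),
    n = as.integer(tapply(e, true_D, length)))
  model$residual_stats <- rs
  model
}

#' @export
print.fsa_correction <- function(x, ...) {
  cat("cmFSA bias-correction model\n")
  cat(sprintf("  D ~ d * exp(sum alpha_l d^l), exponents {%s}\n",
              paste(x$exponents, collapse = ", ")))
  cat(sprintf("  coefficients: %s\n",
              paste(signif(x$coeffs, 5), collapse = ", ")))
  cat(sprintf("  calibrated at n = %s, k = %s, true D in [%g, %g] (%s)\n",
              x$n_cal, x$k_cal, x$d_range[1], x$d_range[2], x$fit_method))
  invisible(x)
}

#' @export
coef.fsa_correction <- function(object, ...) {
  stats::setNames(object$coeffs, paste0("d^", object$exponents))
}

#' Apply the bias correction to a biased estimate
#'
#' Computes \eqn{C(d) = d \exp(\sum_l \alpha_l d^l)}. By construction
#' \eqn{C(d)/d \to 1} and \eqn{C'(d) \to 1} as \eqn{d \to 0} when all
#' exponents are >= 1, so small estimates are left essentially untouched.
#' A warning (not an error) is raised when `d` lies outside the range of
#' estimates seen during calibration, where the polynomial extrapolates.
#'
#' `predict.fsa_correction` is the method interface to the same computation.
#'
#' @param d biased estimate(s), positive.
#' @param model an [fsa_correction] model.
#' @param warn warn on extrapolation outside the calibration estimate range.
#' @return Corrected estimate(s).
#' @export
apply_correction <- function(d, model, warn = TRUE) {
  stopifnot(inherits(model, "fsa_correction"))
  if (any(d <= 0)) stop("d must be positive")
  if (warn && !is.null(model$est_range) &&
      any(d < model$est_range[1] | d > model$est_range[2]))
    warning("estimate outside the calibration range; the correction extrapolates")
  X <- correction_design(d, model$exponents)
  d * exp(drop(X %*% model$coeffs))
}

#' @param object an [fsa_correction] model.
#' @param newdata biased estimate(s) to correct.
#' @param ... unused.
#' @rdname apply_correction
#' @export
predict.fsa_correction <- function(object, newdata, ...) {
  apply_correction(newdata, object)
}

#' Calibrate the bias correction on uniform hypercubes
#'
#' Runs the calibration protocol: for each integer dimension on a grid,
#' generate `n_realizations` uniform hypercube samples of `n` points with a
#' hard boundary (the correction exists precisely to absorb edge and
#' finite-sample effects), compute the median estimate at neighborhood `k`
#' for each realization, and fit the correction model on the pooled
#' (dimension, estimate) pairs. The fitted coefficients depend on `n` and
#' `k`; a model should be applied at the sample size and neighborhood it was
#' calibrated for.
#'
#' @param n calibration sample size per hypercube.
#' @param k neighborhood size.
#' @param d_min,d_max inclusive range of true calibration dimensions.
#' @param n_realizations hypercube realizations per dimension (at least 15
#'   recommended).
#' @param exponents,method passed to [fit_correction()].
#' @param d_step grid step over dimensions (a thinned grid, e.g. every 2nd
#'   dimension, trades calibration density for speed).
#' @param boundary boundary convention for the calibration hypercubes.
#' @param seed integer seed making the calibration reproducible.
#' @return An [fsa_correction] model.
#' @export
calibrate_correction <- function(n, k, d_min = 2, d_max = 80,
                                 n_realizations = 15,
                                 exponents = c(-1, 1, 2, 3),
                                 method = c("ols_all", "odr_means"),
                                 d_step = 1, boundary = "hard", seed = NULL) {
  method <- match.arg(method)
  if (d_max <= d_min) stop("d_max must exceed d_min")
  if (n_realizations < 1) stop("need at least one realization per dimension")
  dims <- seq(as.integer(d_min), as.integer(d_max), by = as.integer(d_step))
  run <- function() {
    recs <- lapply(dims, function(D) {
      est <- vapply(seq_len(n_realizations), function(i) {
        pc <- sample_hypercube(n, D, boundary = boundary)
        fsa(pc, k = k, statistic = "median", keep_local = FALSE)$estimates$estimate
      }, numeric(1))
      data.frame(true_D = D, estimate = est)
    })
    do.call(rbind, recs)
  }
  cal <- if (is.null(seed)) run() else with_seed(seed, run())
  fit_correction(cal$true_D, cal$estimate, exponents = exponents,
                 method = method, n_cal = n, k_cal = k,
                 seed = seed %||% NA_integer_)
}

#' Corrected median estimate of intrinsic dimension (cmFSA)
#'
#' The one-shot corrected estimator: compute the median (mFSA) estimate of a
#' cloud at neighborhood `k`, pass it through a calibrated correction model,
#' and optionally round to the nearest integer (halves away from zero). A
#' warning is raised when the model was calibrated at a different `k` or a
#' clearly different sample size, since the coefficients are (n, k) specific.
#'
#' @inheritParams fsa
#' @param k neighborhood size (single value).
#' @param model an [fsa_correction] model.
#' @param mode `"fractal"` (real-valued) or `"integer"`.
#' @return A `global_estimate` whose `value` is the corrected estimate.
#' @export
cmfsa <- function(x, k, model, mode = c("fractal", "integer"),
                  boundary = "hard") {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "fsa_correction"))
  cloud <- as_point_cloud(x, boundary)
  k <- as.integer(k)
  if (!is.na(model$k_cal) && model$k_cal != k)
    warning(sprintf("model calibrated at k = %d but applied at k = %d",
                    model$k_cal, k))
  n <- nrow(cloud$coords)
  if (!is.na(model$n_cal) && abs(n - model$n_cal) > 0.1 * model$n_cal)
    warning(sprintf("model calibrated at n = %d but applied at n = %d",
                    model$n_cal, n))
  raw <- fsa(cloud, k = k, statistic = "median", keep_local = FALSE)
  val <- apply_correction(raw$estimates$estimate, model)
  if (mode == "integer") val <- round_half_away(val)
  g <- global_estimate(val, "median", k, raw$estimates$n_effective)
  g$corrected <- TRUE
  g$mode <- mode
  g
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Ideal error rate of the integer-mode corrected estimator
#'
#' If the corrected estimate for a manifold of true dimension D is normally
#' distributed, the probability that it rounds to the wrong integer is
#' \deqn{1 - [\Phi((D + 0.5 - \mu)/\sigma) - \Phi((D - 0.5 - \mu)/\sigma)].}
#' The mean and standard deviation are taken from the per-dimension residual
#' statistics stored during calibration (log relative errors `e` with moments
#' \eqn{\mu_e, \sigma_e} imply \eqn{\mu = D e^{-\mu_e}},
#' \eqn{\sigma = \mu \sigma_e} to first order), or can be supplied directly.
#'
#' @param model an [fsa_correction] with residual statistics (or `NULL` when
#'   `mu` and `sigma` are given directly).
#' @param true_D the true dimension.
#' @param mu,sigma optional explicit mean and sd of the corrected estimate,
#'   overriding the model's residual statistics.
#' @return The miss probability in `[0, 1]`.
#' @export
ideal_error_rate <- function(model = NULL, true_D, mu = NULL, sigma = NULL) {
  if (is.null(mu) || is.null(sigma)) {
    stopifnot(inherits(model, "fsa_correction"))
    rs <- model$residual_stats
    if (is.null(rs)) stop("model carries no residual statistics")
    row <- rs[rs$true_D == true_D, ]
    if (nrow(row) != 1L)
      stop(sprintf("no residual statistics stored for D = %s", true_D))
    mu <- true_D * exp(-row$mean_log_err)
    sigma <- mu * row$sd_log_err
  }
  if (sigma == 0) return(as.numeric(round_half_away(mu) != true_D))
  1 - (pnorm((true_D + 0.5 - mu) / sigma) - pnorm((true_D - 0.5 - mu) / sigma))
}

#' Serialize a correction model as structured text
#'
#' Writes/reads the model as JSON: exponents, coefficients, calibration
#' sample size and neighborhood, dimension range, fit method, residual
#' statistics, seed and tool version.
#'
#' @param model an [fsa_correction] model.
#' @param path file path.
#' @return `write_correction_model` returns `path` invisibly;
#'   `read_correction_model` returns the model.
#' @export
write_correction_model <- function(model, path) {
  stopifnot(inherits(model, "fsa_correction"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_correction_model
#' @export
read_correction_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(
    list(exponents = as.numeric(x$exponents), coeffs = as.numeric(x$coeffs),
         n_cal = as.integer(x$n_cal %||% NA), k_cal = as.integer(x$k_cal %||% NA),
         d_range = as.numeric(x$d_range), fit_method = x$fit_method,
         est_range = as.numeric(x$est_range),
         seed = x$seed %||% NA_integer_,
         residual_stats = if (!is.null(x$residual_stats))
           as.data.frame(x$residual_stats) else NULL,
         version = x$version %||% NA_character_),
    class = "fsa_correction")
  model
}
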