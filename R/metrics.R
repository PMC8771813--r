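#' Mean percentage error over manifolds and realizations
#'
#' \deqn{MPE = \frac{100}{MN} \sum_{j=1}^M \sum_{i=1}^N
#'   \frac{|D_j - d_{ij}|}{D_j}}
#' for M manifold types with N realizations each.
#'
#' @param estimates an M x N matrix of estimates (rows = manifolds), or a
#'   list of numeric vectors (one per manifold, ragged lengths allowed).
#' @param true_dims length-M vector of true dimensions, all positive.
#' @return The MPE as a percentage.
#' @export
mpe <- function(estimates, true_dims) {
  if (is.matrix(estimates)) estimates <- split(estimates, row(estimates))
  if (!is.list(estimates)) estimates <- list(estimates)
  if (length(estimates) != length(true_dims))
    stop("one true dimension per manifold is required")
  if (any(true_dims <= 0)) stop("true dimensions must be positive")
  per <- mapply(function(d, D) abs(D - d) / D, estimates, true_dims,
                SIMPLIFY = FALSE)
  100 * mean(unlist(per))
}

#' Integer-mode error rate
#'
#' Fraction of realizations whose integer estimate misses the true dimension,
#' \eqn{H_j = N^{-1} \sum_i I(D_j \ne d_{ij})}; `mean_error_rate()` averages
#' the per-manifold rates without weighting. Non-integer estimates are
#' rounded first (halves away from zero).
#'
#' @param estimates estimates for one manifold (numeric; rounded to integer).
#' @param true_D the manifold's true dimension.
#' @return A fraction in `[0, 1]`.
#' @export
error_rate <- function(estimates, true_D) {
  if (length(estimates) < 1L) stop("no estimates supplied")
  mean(round_half_away(estimates) != true_D)
}

#' @param rates per-manifold error rates.
#' @rdname error_rate
#' @export
mean_error_rate <- function(rates) mean(as.numeric(rates))

sample_manifold <- function(family, n, D, boundary = "hard") {
  switch(family,
         hypercube = sample_hypercube(n, D, boundary = boundary),
         gaussian = sample_gaussian(n, D),
         cauchy_ball = sample_cauchy_ball(n, D),
         sphere_surface = sample_sphere_surface(n, D),
         stop(sprintf("unknown manifold family '%s'", family)))
}

#' Benchmark harness over generated manifolds
#'
#' Generates `n_realizations` samples per manifold specification, estimates
#' the dimension of each with the requested estimator, and aggregates the
#' per-manifold mean estimate, standard deviation, integer-mode error rate,
#' and the overall MPE and mean error rate. Reports are deterministic under a
#' fixed seed.
#'
#' @param specs data frame with columns `family` (one of `"hypercube"`,
#'   `"gaussian"`, `"cauchy_ball"`, `"sphere_surface"`), `D` and `n`; an
#'   optional `boundary` column applies to hypercubes.
#' @param estimator `"mfsa"`, `"fsa_mean"`, `"ml"`, `"levina_bickel"` or
#'   `"cmfsa"` (the latter needs `model`).
#' @param k neighborhood size.
#' @param n_realizations realizations per manifold.
#' @param model an [fsa_correction], required for `estimator = "cmfsa"`.
#' @param mode rounding mode for cmFSA.
#' @param seed integer seed for the whole run.
#' @return An object of class `fsa_benchmark`: list with `results` (one row
#'   per manifold: family, true_D, mean_estimate, sd, error_rate), `raw`
#'   (matrix of all estimates), `mpe` and `mean_error_rate`.
#' @export
run_benchmark <- function(specs, estimator = c("mfsa", "fsa_mean", "ml",
                                               "levina_bickel", "cmfsa"),
                          k = 5, n_realizations = 10, model = NULL,
                          mode = "integer", seed = NULL) {
  estimator <- match.arg(estimator)
  if (estimator == "cmfsa" && is.null(model))
    stop("cmfsa benchmarking needs a correction model")
  specs <- as.data.frame(specs)
  if (!all(c("family", "D", "n") %in% names(specs)))
    stop("specs must have columns family, D, n")
  if (is.null(specs$boundary)) specs$boundary <- "hard"
  one <- function(row) {
    vapply(seq_len(n_realizations), function(i) {
      pc <- sample_manifold(row$family, row$n, row$D, row$boundary)
      switch(estimator,
             mfsa = fsa(pc, k = k, keep_local = FALSE)$estimates$estimate,
             fsa_mean = fsa(pc, k = k, statistic = "mean",
                            keep_local = FALSE)$estimates$estimate,
             ml = fsa(pc, k = k, statistic = "ml",
                      keep_local = FALSE)$estimates$estimate,
             levina_bickel = levina_bickel(pc, k = k)$value,
             cmfsa = suppressWarnings(cmfsa(pc, k = k, model = model,
                                            mode = mode))$value)
    }, numeric(1))
  }
  run <- function() {
    do.call(rbind, lapply(seq_len(nrow(specs)), function(j) one(specs[j, ])))
  }
  raw <- if (is.null(seed)) run() else with_seed(seed, run())
  res <- data.frame(
    family = specs$family, true_D = specs$D, n = specs$n,
    mean_estimate = rowMeans(raw),
    sd = apply(raw, 1, sd),
    error_rate = vapply(seq_len(nrow(specs)),
                        function(j) error_rate(raw[j, ], specs$D[j]),
                        numeric(1)))
  structure(list(results = res, raw = raw,
                 mpe = mpe(raw, specs$D),
                 mean_error_rate = mean_error_rate(res$error_rate),
                 estimator = estimator, k = k,
                 n_realizations = n_realizations, seed = seed),
            class = "fsa_benchmark")
}

#' @export
print.fsa_benchmark <- function(x, digits = 3, ...) {
  cat(sprintf("benchmark: %s estimator, k = %d, N = %d realizations\n",
              x$estimator, x$k, x$n_realizations))
  print(format(x$results, digits = digits), row.names = FALSE)
  cat(sprintf("MPE = %.3f   mean error rate = %.3f\n",
              x$mpe, x$mean_error_rate))
  invisible(x)
}

#' Write a benchmark report as delimited text
#'
#' @param bench an [run_benchmark()] result.
#' @param path output file.
#' @param sep delimiter.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(bench, path, sep = "\t") {
  stopifnot(inherits(bench, "fsa_benchmark"))
  write.table(bench$results, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
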