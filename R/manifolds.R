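# Synthetic manifold samplers used for validation and calibration. All
# samplers are pure functions of their arguments plus the seed: a non-NULL
# seed gives bit-identical output and leaves the caller's RNG state alone.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

maybe_seeded <- function(seed, expr) {
  if (is.null(seed)) expr else with_seed(seed, expr)
}

#' Uniform unit hypercube sample
#'
#' n i.i.d. points uniform on \eqn{[0,1)^D}. These are the calibration and
#' validation datasets of the whole framework: with a periodic boundary the
#' locally-uniform-density assumption holds exactly, with a hard boundary the
#' sample exhibits the edge effect the correction model absorbs.
#'
#' @param n sample count.
#' @param D intrinsic (= ambient) dimension.
#' @param boundary boundary convention attached to the cloud.
#' @param seed optional integer seed (reproducible, RNG-state preserving).
#' @return A [point_cloud].
#' @export
sample_hypercube <- function(n, D, boundary = c("hard", "periodic"),
                             seed = NULL) {
  boundary <- match.arg(boundary)
  x <- maybe_seeded(seed, matrix(runif(n * D), n, D))
  point_cloud(x, boundary = boundary, label = sprintf("uniform %dd hypercube", D))
}

#' Standard multivariate Gaussian sample
#'
#' n i.i.d. points from a zero-mean, identity-covariance D-variate normal
#' (hard boundary). A standard non-uniform-density test case on which the
#' median estimator underestimates at moderate sample sizes.
#'
#' @inheritParams sample_hypercube
#' @export
sample_gaussian <- function(n, D, seed = NULL) {
  x <- maybe_seeded(seed, matrix(rnorm(n * D), n, D))
  point_cloud(x, boundary = "hard", label = sprintf("%dd standard Gaussian", D))
}

#' Cauchy-norm ball sample
#'
#' Heavy-tailed test manifold: directions uniform on the unit sphere in
#' \eqn{R^D} (normalized Gaussians) scaled by radii |standard Cauchy|, so the
#' point norms follow the half-Cauchy law (median 1).
#'
#' @inheritParams sample_hypercube
#' @export
sample_cauchy_ball <- function(n, D, seed = NULL) {
  x <- maybe_seeded(seed, {
    z <- matrix(rnorm(n * D), n, D)
    z <- z / sqrt(rowSums(z^2))
    u <- abs(rcauchy(n))
    z * u
  })
  point_cloud(x, boundary = "hard", label = sprintf("%dd Cauchy ball", D))
}

#' Uniform hypersphere-surface sample
#'
#' n points uniform on the unit sphere surface: intrinsic dimension D,
#' ambient dimension D + 1. Obtained by normalizing (D+1)-variate standard
#' Gaussians. A mildly curved test manifold.
#'
#' @inheritParams sample_hypercube
#' @export
sample_sphere_surface <- function(n, D, seed = NULL) {
  x <- maybe_seeded(seed, {
    z <- matrix(rnorm(n * (D + 1)), n, D + 1)
    z / sqrt(rowSums(z^2))
  })
  point_cloud(x, boundary = "hard", label = sprintf("%dd sphere surface", D))
}

#' Coupled logistic-map simulator
#'
#' Three chaotic logistic maps where two independent variables drive a third:
#' \deqn{x_{t+1} = r_x x_t (1 - x_t), \quad y_{t+1} = r_y y_t (1 - y_t),}
#' \deqn{z_{t+1} = r_z z_t (1 - z_t - \beta_{zx} x_t - \beta_{zy} y_t).}
#' The driven update can leave \eqn{[0,1]}; with `wrap = TRUE` (default) the
#' state is wrapped modulo 1 each step, giving a periodic state space on
#' \eqn{[0,1)} whose embedded attractor can be measured with periodic
#' distances. Initial states are drawn uniform in (0, 1) and a transient is
#' discarded before emitting samples. The z-dynamics is approximately three
#' dimensional (one driven plus two driving degrees of freedom).
#'
#' @param n output length after the transient.
#' @param r growth rates `c(r_x, r_y, r_z)`.
#' @param beta coupling strengths `c(beta_zx, beta_zy)`.
#' @param transient discarded initial steps (chaotic burn-in).
#' @param wrap wrap states into `[0, 1)` each step.
#' @param init optional initial state `c(x0, y0, z0)` overriding the random
#'   draw.
#' @param seed optional integer seed.
#' @return A data frame with columns `x`, `y`, `z` of length `n`.
#' @export
simulate_coupled_logistic <- function(n, r = c(3.99, 3.99, 3.99),
                                      beta = c(0.3, 0.3), transient = 1000,
                                      wrap = TRUE, init = NULL, seed = NULL) {
  stopifnot(n >= 1, transient >= 0, length(r) == 3, length(beta) == 2)
  maybe_seeded(seed, {
    s <- if (is.null(init)) runif(3) else as.numeric(init)
    x <- s[1]; y <- s[2]; z <- s[3]
    total <- n + transient
    out <- matrix(NA_real_, total, 3)
    for (t in seq_len(total)) {
      xn <- r[1] * x * (1 - x)
      yn <- r[2] * y * (1 - y)
      zn <- r[3] * z * (1 - z - beta[1] * x - beta[2] * y)
      if (wrap) {
        xn <- xn %% 1; yn <- yn %% 1; zn <- zn %% 1
      }
      x <- xn; y <- yn; z <- zn
      out[t, ] <- c(x, y, z)
    }
    out <- out[(transient + 1):total, , drop = FALSE]
    data.frame(x = out[, 1], y = out[, 2], z = out[, 3])
  })
}

#' Time-delay embedding of a scalar series
#'
#' Reconstructs a state-space trajectory from a scalar time series:
#' \deqn{X(t) = [x(t), x(t-\tau), \ldots, x(t-(E-1)\tau)].}
#' Row t of the result holds the E delayed coordinates of time t; the first
#' \eqn{(E-1)\tau} times are dropped, so a series of length L yields
#' \eqn{L - (E-1)\tau} rows.
#'
#' @param series numeric time series.
#' @param E embedding dimension (>= 1).
#' @param tau embedding delay (>= 1).
#' @param boundary boundary convention attached to the embedded cloud
#'   (`"periodic"` for series living on the unit circle, such as the wrapped
#'   logistic maps).
#' @return A [point_cloud] with E columns.
#' @export
delay_embed <- function(series, E, tau = 1, boundary = c("hard", "periodic")) {
  boundary <- match.arg(boundary)
  series <- as.numeric(series)
  E <- as.integer(E); tau <- as.integer(tau)
  if (E < 1L || tau < 1L) stop("E and tau must be positive integers")
  L <- length(series)
  span <- (E - 1L) * tau
  if (L < span + 1L)
    stop(sprintf("series too short: need at least %d values for E = %d, tau = %d",
                 span + 1L, E, tau))
  rows <- L - span
  X <- vapply(0:(E - 1L),
              function(j) series[(span + 1L - j * tau):(L - j * tau)],
              numeric(rows))
  point_cloud(matrix(X, nrow = rows), boundary = boundary,
              label = sprintf("delay embedding (E = %d, tau = %d)", E, tau))
}
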