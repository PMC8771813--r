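test_that("the closed-form single-coefficient fit is exact arithmetic", {
  expect_equal(fit_alpha_closed_form(c(2, 4), c(2, 4)), 0)   # unbiased data
  expect_equal(fit_alpha_closed_form(c(2, 5), c(2, 4)),
               log(1.25) * 4 / 20, tolerance = 1e-12)
  expect_error(fit_alpha_closed_form(2, -1), "positive")
})

test_that("the closed form recovers a known coefficient under noise", {
  set.seed(51)
  alpha <- 0.03
  D <- rep(2:25, each = 20)
  d <- vapply(D, function(Di) {
    f <- function(x) x * exp(alpha * x) - Di
    stats::uniroot(f, c(0.1, Di))$root
  }, numeric(1))
  d <- d * exp(rnorm(length(d), 0, 0.01))   # multiplicative noise
  expect_equal(fit_alpha_closed_form(D, d), alpha, tolerance = 0.003)
})

test_that("exponent-{1} OLS reproduces the closed form through the same normal equations", {
  set.seed(52)
  D <- rep(c(3, 7, 12, 20), each = 5)
  d <- D * exp(rnorm(20, 0, 0.05)) * 0.9
  m <- fit_correction(D, d, exponents = 1, method = "ols_all")
  expect_equal(unname(coef(m)), fit_alpha_closed_form(D, d), tolerance = 1e-12)
})

test_that("noise-free multi-exponent data is recovered exactly by both fits", {
  alpha <- c(-0.05, 0.02, -3e-4)
  exps <- c(-1, 1, 2)
  d <- rep(seq(2, 30, by = 2), each = 3)
  D <- d * exp(colSums(alpha * t(outer(d, exps, "^"))))
  for (method in c("ols_all", "odr_means")) {
    m <- fit_correction(D, d, exponents = exps, method = method)
    expect_equal(unname(coef(m)), alpha, tolerance = 1e-10)
  }
  expect_error(fit_correction(rep(5, 4), runif(4, 4, 5), exponents = 1),
               "distinct")
})

test_that("applying the correction is the exponential-polynomial map", {
  identity_model <- fit_correction(c(1, 2), c(1, 2), exponents = 1)
  expect_equal(unname(coef(identity_model)), 0, tolerance = 1e-12)
  expect_equal(apply_correction(3.7, identity_model, warn = FALSE), 3.7)
  m <- structure(list(exponents = 1, coeffs = 0.044629, est_range = c(1, 10)),
                 class = "fsa_correction")
  expect_equal(apply_correction(2, m), 2 * exp(0.089258), tolerance = 1e-6)
  # strictly increasing whenever coefficients >= 0 and exponents >= 1
  m2 <- structure(list(exponents = c(1, 2), coeffs = c(0.03, 1e-4),
                       est_range = c(0, 100)), class = "fsa_correction")
  d <- seq(0.1, 50, by = 0.1)
  expect_true(all(diff(apply_correction(d, m2)) > 0))
  # small-d limit: C(d)/d -> 1
  expect_equal(apply_correction(1e-8, m2) / 1e-8, 1, tolerance = 1e-6)
  expect_warning(apply_correction(500, m2), "extrapolates")
})

test_that("hypercube calibration is reproducible and validates its inputs", {
  m1 <- calibrate_correction(150, 1, d_min = 2, d_max = 6, n_realizations = 3,
                             exponents = 1, d_step = 2, seed = 53)
  m2 <- calibrate_correction(150, 1, d_min = 2, d_max = 6, n_realizations = 3,
                             exponents = 1, d_step = 2, seed = 53)
  expect_identical(coef(m1), coef(m2))
  expect_identical(m1$residual_stats, m2$residual_stats)
  expect_gt(unname(coef(m1)), 0)   # hard boundary biases downward
  expect_error(calibrate_correction(150, 1, d_min = 5, d_max = 5,
                                    n_realizations = 3), "exceed")
})

test_that("cmfsa corrects, rounds and warns on mismatched calibration", {
  identity_model <- fit_correction(c(1, 2), c(1, 2), exponents = 1,
                                   n_cal = 300, k_cal = 2)
  pc <- sample_hypercube(300, 3, seed = 54)
  raw <- fsa(pc, k = 2)$estimates$estimate
  est <- suppressWarnings(cmfsa(pc, k = 2, model = identity_model,
                                mode = "integer"))
  expect_equal(est$value, round(raw))
  w <- capture_warnings(cmfsa(pc, k = 3, model = identity_model))
  expect_match(w, "calibrated at k", all = FALSE)
  expect_equal(fsadim:::round_half_away(3.5), 4)
  expect_equal(fsadim:::round_half_away(2.5), 3)   # halves away from zero
  expect_equal(fsadim:::round_half_away(3.4), 3)
})

test_that("the ideal error rate is the normal two-sided miss probability", {
  expect_equal(ideal_error_rate(true_D = 10, mu = 10, sigma = 1e-12), 0)
  expect_equal(ideal_error_rate(true_D = 10, mu = 10, sigma = 0.5),
               1 - (pnorm(1) - pnorm(-1)), tolerance = 1e-12)
  set.seed(55)
  mu <- 9.8; sigma <- 0.4; D <- 10
  draws <- rnorm(1e5, mu, sigma)
  mc <- mean(round(draws) != D)
  expect_equal(ideal_error_rate(true_D = D, mu = mu, sigma = sigma), mc,
               tolerance = 5e-3)
  m <- calibrate_correction(150, 1, d_min = 2, d_max = 6, n_realizations = 5,
                            exponents = 1, d_step = 2, seed = 56)
  rate <- ideal_error_rate(m, true_D = 4)
  expect_true(rate >= 0 && rate <= 1)
  expect_error(ideal_error_rate(m, true_D = 33), "no residual statistics")
})

test_that("correction models round-trip through JSON text", {
  m <- calibrate_correction(150, 1, d_min = 2, d_max = 6, n_realizations = 3,
                            exponents = c(-1, 1), d_step = 2, seed = 57)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_correction_model(m, path)
  back <- read_correction_model(path)
  expect_equal(coef(back), coef(m), tolerance = 1e-14)
  expect_equal(back$d_range, m$d_range)
  expect_equal(back$fit_method, m$fit_method)
  expect_equal(back$residual_stats$sd_log_err, m$residual_stats$sd_log_err,
               tolerance = 1e-14)
  # a reloaded model predicts identically
  expect_equal(apply_correction(4.2, back, warn = FALSE),
               apply_correction(4.2, m, warn = FALSE), tolerance = 1e-14)
})
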