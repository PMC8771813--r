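test_that("normalized-distance density matches its closed form and normalizes", {
  # k = 1 of K = 2 neighbors in one dimension: flat density on [0, 1]
  r <- seq(0.05, 0.95, by = 0.1)
  expect_equal(dknn_ratio(r, 1, 2, 1), rep(1, length(r)))
  for (case in list(c(1, 2, 3), c(3, 6, 5), c(5, 10, 2))) {
    total <- integrate(dknn_ratio, 0, 1, k = case[1], K = case[2], D = case[3],
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  expect_error(dknn_ratio(0.5, 3, 3, 2), "k < K")
})

test_that("the local-estimate density is the K = 2k ratio law after a Jacobian", {
  D <- 3; k <- 4
  delta <- c(0.5, 1, 2, 3, 4.5, 8)
  r <- 2^(-1 / delta)                      # delta = -ln2 / ln r
  jac <- r * log(2) / delta^2              # |dr/ddelta|
  expect_equal(dfsa(delta, D, k), dknn_ratio(r, k, 2 * k, D) * jac,
               tolerance = 1e-12)
})

test_that("the local-estimate pdf evaluates, normalizes, and matches k = 1 forms", {
  expect_equal(dfsa(1, D = 1, k = 1), log(2) / 2, tolerance = 1e-12)
  # the k = 1 closed-form branch agrees with the general-beta expression
  delta <- c(0.3, 1, 2.7, 10)
  general <- exp(log(2) + log(log(2)) - lbeta(1, 1) -
                 (2 / delta) * log(2) - 2 * log(delta))
  expect_equal(dfsa(delta, D = 2, k = 1), general, tolerance = 1e-12)
  for (D in c(2, 5, 12)) {
    for (k in c(1, 11, 50)) {
      total <- integrate(dfsa, 0, Inf, D = D, k = k, rel.tol = 1e-8)$value
      expect_equal(total, 1, tolerance = 1e-6)
    }
  }
  expect_error(dfsa(-1, 2, 1), "positive")
})

test_that("the cdf has median exactly at D and the right limits", {
  for (D in c(1, 2, 5, 12)) {
    for (k in c(1, 3, 11, 50)) {
      expect_equal(pfsa(D, D, k), 0.5, tolerance = 1e-10)
    }
  }
  expect_equal(pfsa(1e-8, 3, 2), 0, tolerance = 1e-12)
  expect_equal(pfsa(1e8, 3, 2), 1, tolerance = 1e-6)
  expect_equal(pfsa(2, 2, 1), 0.5)               # k = 1 closed form 2^(-D/delta)
  expect_equal(pfsa(1, 2, 1), 0.25)
})

test_that("the cdf equals the integral of the pdf", {
  D <- 4; k <- 7
  for (delta in c(0.5, 2, 4, 6, 12)) {
    num <- integrate(dfsa, 0, delta, D = D, k = k, rel.tol = 1e-12)$value
    expect_equal(pfsa(delta, D, k), num, tolerance = 1e-8)
  }
})

test_that("quantiles invert the cdf and draws follow the law", {
  p <- c(0.01, 0.25, 0.5, 0.9, 0.99)
  expect_equal(pfsa(qfsa(p, 6, 9), 6, 9), p, tolerance = 1e-10)
  expect_equal(qfsa(0.5, 7, 13), 7, tolerance = 1e-10)
  set.seed(41)
  draws <- rfsa(2e4, 3, 4)
  ks <- suppressWarnings(stats::ks.test(pfsa(draws, 3, 4), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the beta transform maps the law onto Beta(k, k)", {
  expect_equal(a_transform(5, 5), 0.5)
  expect_equal(a_transform(1e12, 3), 1, tolerance = 1e-9)
  set.seed(42)
  a <- a_transform(rfsa(1e5, 3, 4), 3)
  ks <- suppressWarnings(stats::ks.test(a, stats::pbeta, 4, 4))
  expect_gt(ks$p.value, 0.01)
})

test_that("the median sampling density reduces, normalizes and concentrates", {
  d <- c(0.5, 1.5, 2, 3, 7)
  expect_equal(dfsa_median(d, 2, 3, 1), dfsa(d, 2, 3), tolerance = 1e-12)
  for (case in list(c(2, 1, 11), c(5, 1, 101), c(5, 3, 1001))) {
    total <- integrate(dfsa_median, 0, Inf, D = case[1], k = case[2],
                       n = case[3], rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  expect_error(dfsa_median(1, 2, 1, 10), "odd")
  # mode approaches D and the spread shrinks as n grows
  grid <- seq(0.5, 8, by = 1e-3)
  modes <- ses <- numeric(3)
  for (i in seq_along(c(11, 101, 1001))) {
    n <- c(11, 101, 1001)[i]
    modes[i] <- grid[which.max(dfsa_median(grid, 2, 1, n))]
    ses[i] <- median_se_numeric(2, 1, n)
  }
  expect_true(all(diff(abs(modes - 2)) <= 0))
  expect_true(all(diff(ses) < 0))
  expect_equal(modes[3], 2, tolerance = 0.05)
})

test_that("the numeric median SE matches Monte-Carlo simulation", {
  set.seed(43)
  D <- 2; k <- 3; n <- 11
  meds <- replicate(4e4, median(-D * log(2) / log(rbeta(n, k, k))))
  expect_equal(median_se_numeric(D, k, n), sd(meds), tolerance = 0.03)
})

test_that("the median SE obeys its scaling laws", {
  # relative error sigma/D independent of D (exact scaling in D)
  rel <- vapply(c(2, 5, 10),
                function(D) median_se_numeric(D, 5, 101) / D, numeric(1))
  expect_lt(max(rel) - min(rel), 1e-3)
  # Laplace-Stirling approximation accurate for k > 10
  for (k in c(11, 25, 51)) {
    ratio <- median_se_approx(5, k, 101) / median_se_numeric(5, k, 101)
    expect_true(ratio > 0.95 && ratio < 1.05)
  }
  # closed form: doubling n*k divides the value by sqrt(2) exactly
  expect_equal(median_se_approx(5, 2, 500) / sqrt(2),
               median_se_approx(5, 2, 1000), tolerance = 1e-12)
  expect_equal(median_se_approx(5, 1, 1001),
               sqrt(pi) / (2 * log(2)) * 5 / sqrt(1001), tolerance = 1e-12)
})

test_that("the expected local estimate follows the hyperbola in k", {
  expect_error(expected_delta(2, 1), "diverges")
  # frozen quadrature value: E[delta_2] at D = 2 (cross-checks a ~ 0.685)
  expect_equal(expected_delta(2, 2), 3.372564, tolerance = 1e-5)
  expect_equal(expected_delta(2, 500), 2, tolerance = 0.005 * 2)
  expect_equal(hyperbola_constant(D = 2, k_range = 2:50), 0.6808547,
               tolerance = 1e-4)
})
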