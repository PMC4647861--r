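# Fixed-intercept slope estimation and series summaries.

test_that("closed-form slopes match hand calculations", {
  # exact affine data: slope 5, zero residuals
  tr <- fit_fixed_intercept_slope(c(2, 4, 6), c(110, 120, 130), 100)
  expect_equal(tr$slope, 5)
  expect_equal(tr$slope_variance, 0)
  expect_equal(tr$residual_variance, 0)
  # constant series: slope 0
  tr0 <- fit_fixed_intercept_slope(c(2, 4, 6), c(100, 100, 100), 100)
  expect_equal(tr0$slope, 0)
  expect_equal(tr0$slope_variance, 0)
  # noisy case, hand least squares: b = sum(t dy)/sum(t^2) = 288/56 = 36/7;
  # SSR = (12/7)^2 + (18/7)^2 + (8/7)^2 = 532/49, df = n - 1 = 2,
  # slope var = (532/98)/56 = 532/5488
  tr2 <- fit_fixed_intercept_slope(c(2, 4, 6), c(112, 118, 132), 100)
  expect_equal(tr2$slope, 36 / 7)
  expect_equal(tr2$residual_variance, 532 / 49 / 2)
  expect_equal(tr2$slope_variance, 532 / 5488)
})

test_that("estimator agrees with a no-intercept regression on the offsets", {
  set.seed(41)
  for (k in 1:5) {
    t <- c(2, 4, 6)
    y0 <- runif(1, 50, 150)
    y <- y0 + runif(1, -2, 8) * t + rnorm(3)
    tr <- fit_fixed_intercept_slope(t, y, y0)
    ref <- summary(lm(I(y - y0) ~ 0 + t))
    expect_equal(tr$slope, unname(coef(ref)[1, "Estimate"]), tolerance = 1e-12)
    expect_equal(sqrt(tr$slope_variance),
                 unname(coef(ref)[1, "Std. Error"]), tolerance = 1e-12)
  }
})

test_that("slope minimises SSR (parabola-vertex oracle)", {
  set.seed(42)
  for (k in 1:10) {
    t <- sort(runif(sample(3:6, 1), 0.5, 6))
    y0 <- runif(1, 0, 100)
    y <- y0 + runif(1, -5, 10) * t + rnorm(length(t), sd = 2)
    tr <- fit_fixed_intercept_slope(t, y, y0)
    # SSR(b) is quadratic in b; its vertex from three evaluations is the
    # exact minimiser, independent of the estimator's formula
    ssr <- function(b) sum((y - y0 - b * t)^2)
    s0 <- ssr(0); s1 <- ssr(1); s2 <- ssr(2)
    vertex <- 1 + (s0 - s2) / (2 * (s0 - 2 * s1 + s2))
    expect_equal(tr$slope, vertex, tolerance = 1e-9)
  }
})

test_that("estimator is linear and offset-invariant", {
  t <- c(1, 2.5, 4, 6)
  y0 <- 20
  y <- y0 + 3 * t + c(0.5, -0.2, 0.3, -0.4)
  b <- fit_fixed_intercept_slope(t, y, y0)$slope
  expect_equal(fit_fixed_intercept_slope(t, 2.5 * y, 2.5 * y0)$slope, 2.5 * b)
  expect_equal(fit_fixed_intercept_slope(t, y + 7, y0 + 7)$slope, b)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_fixed_intercept_slope(2, 110, 100),
               class = "phepart_degenerate_fit")
  expect_error(fit_fixed_intercept_slope(c(0, 0), c(1, 2), 0),
               class = "phepart_degenerate_fit")
})

test_that("trend evaluation is affine on the grid", {
  tr <- linear_trend(5, 100)
  expect_equal(evaluate_trend(tr, c(0, 3, 6)), c(100, 115, 130))
  expect_equal(evaluate_trend(linear_trend(0, 7), 1:5), rep(7, 5))
  g <- seq(0, 6, by = 0.1)
  v <- evaluate_trend(tr, g)
  expect_length(v, 61)
  expect_equal(v[1], 100)
  expect_equal(v[61], 130)
  expect_error(evaluate_trend(tr, numeric(0)), class = "phepart_empty_grid")
})

test_that("tyrosine labelling is summarised by its mean and variance of mean", {
  m <- mean_tyrosine_labelling(c(0.84, 0.86, 0.85))
  expect_equal(m$mean, 0.85)
  expect_equal(m$variance, var(c(0.84, 0.86, 0.85)) / 3)
  one <- mean_tyrosine_labelling(0.8)
  expect_equal(one$mean, 0.8)
  expect_equal(one$variance, 0)
  const <- mean_tyrosine_labelling(rep(0.9, 4))
  expect_equal(const$mean, 0.9)
  expect_equal(const$variance, 0)
  expect_error(mean_tyrosine_labelling(numeric(0)),
               class = "phepart_empty_series")
  expect_error(mean_tyrosine_labelling(c(0.5, 1.2)),
               class = "phepart_fraction_range")
})

test_that("consumption rate is the fixed-origin slope of cumulative emission", {
  vc <- estimate_consumption_rate(c(2, 4, 6), c(20, 40, 60))
  expect_equal(vc$slope, 10)
  expect_equal(vc$slope_variance, 0)
  expect_equal(estimate_consumption_rate(c(2, 4, 6), c(0, 0, 0))$slope, 0)
  # linearity in the emission values
  e <- c(18, 43, 59)
  expect_equal(estimate_consumption_rate(c(2, 4, 6), 2 * e)$slope,
               2 * estimate_consumption_rate(c(2, 4, 6), e)$slope)
  expect_warning(estimate_consumption_rate(c(2, 4, 6), c(20, 15, 40)),
                 "decreases")
  expect_error(
    estimate_consumption_rate(c(2, 4, 6), c(20, 15, 40), strict = TRUE),
    class = "phepart_nonmonotone_emission")
})
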