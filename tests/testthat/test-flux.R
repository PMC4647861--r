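# Mass-balance flux model: inversion, limits, conservation, summaries.

test_that("labelled-pool rate follows the product rule", {
  expect_equal(product_rate(110, 5, 0.04, 0.02), 2.4)
  expect_equal(product_rate(123, -7, 0, 0), 0)
  expect_equal(product_rate(110, 0, 0.3, 0), 0)
  expect_error(product_rate(110, 5, 1.4, 0.02),
               class = "phepart_fraction_range")
})

test_that("flux inversion reproduces the worked substitution", {
  pool <- linear_trend(5, 100)
  frac <- linear_trend(0.02, 0)
  tr <- compute_fluxes(pool, frac, f_tyr = 0.8, vc = 10, grid = c(0, 6))
  # t0: v2 = (100 * 0.02 + 0) / 0.8 = 2.5, v1 = 5 - 2.5 + 10 = 12.5
  # t6: v2 = (0.12*5 + 130*0.02 + 10*0.12) / 0.8 = 5.5, v1 = 9.5
  expect_equal(tr$v2, c(2.5, 5.5))
  expect_equal(tr$v1, c(12.5, 9.5))
  expect_equal(tr$vc, 10)
})

test_that("zero-enrichment and full-label limits hold exactly", {
  pool <- linear_trend(4, 120)
  grid <- seq(0, 6, by = 0.5)
  # f == 0: no label ever enters the pool, so v2 == 0
  none <- compute_fluxes(pool, linear_trend(0, 0), 0.85, 8, grid)
  expect_equal(none$v2, rep(0, length(grid)))
  expect_equal(none$v1, rep(4 + 8, length(grid)))
  # f == fTyr: everything is made via the tyrosine-donor route, v1 == 0
  all_lab <- compute_fluxes(pool, linear_trend(0, 0.85), 0.85, 8, grid)
  expect_equal(all_lab$v2, rep(4 + 8, length(grid)))
  expect_equal(all_lab$v1, rep(0, length(grid)))
})

test_that("conservation identity holds on random inputs", {
  set.seed(7)
  grid <- seq(0, 6, by = 0.1)
  for (k in 1:25) {
    pool <- linear_trend(runif(1, -3, 8), runif(1, 50, 200))
    frac <- linear_trend(runif(1, 0, 0.02), runif(1, 0, 0.05))
    vc <- runif(1, 0, 20)
    tr <- suppressWarnings(
      compute_fluxes(pool, frac, runif(1, 0.5, 1), vc, grid))
    lhs <- tr$v1 + tr$v2 - tr$vc
    expect_lt(max(abs(lhs - pool$slope) / max(1, abs(pool$slope))), 1e-12)
  }
})

test_that("fluxes are homogeneous in the concentration scale", {
  grid <- seq(0, 6, by = 0.2)
  kscale <- 3.7
  a <- compute_fluxes(linear_trend(5, 100), linear_trend(0.009, 0),
                      0.85, 10, grid)
  b <- compute_fluxes(linear_trend(5 * kscale, 100 * kscale),
                      linear_trend(0.009, 0), 0.85, 10 * kscale, grid)
  expect_equal(b$v1, kscale * a$v1)
  expect_equal(b$v2, kscale * a$v2)
  expect_equal(b$v2 / b$v1, a$v2 / a$v1)
})

test_that("v2 decreases as the tyrosine plateau rises", {
  grid <- c(0, 3, 6)
  fts <- seq(0.5, 0.95, by = 0.05)
  v2s <- sapply(fts, function(ft) {
    compute_fluxes(linear_trend(5, 100), linear_trend(0.009, 0),
                   ft, 10, grid)$v2[2]
  })
  expect_true(all(diff(v2s) < 0))
})

test_that("a non-positive tyrosine plateau is a hard error", {
  expect_error(
    compute_fluxes(linear_trend(5, 100), linear_trend(0.009, 0), 0, 10),
    class = "phepart_ftyr_nonpositive")
})

test_that("negative flux estimates warn but are not clipped", {
  # huge vc drives v1 negative at late times
  expect_warning(
    tr <- compute_fluxes(linear_trend(1, 100), linear_trend(0.05, 0),
                         0.3, 2, grid = c(0, 6)),
    "negative")
  expect_equal(tr$v1 + tr$v2 - tr$vc, rep(1, 2))
})

test_that("ratio and percent-change summaries behave", {
  pool <- linear_trend(5, 100)
  frac <- linear_trend(0.02, 0)
  tr <- compute_fluxes(pool, frac, 0.8, 10, grid = c(0, 6))
  expect_equal(flux_ratio(tr, 6), 5.5 / 9.5)
  expect_error(flux_ratio(tr, 3), class = "phepart_grid_mismatch")
  zero2 <- compute_fluxes(pool, linear_trend(0, 0), 0.8, 10, grid = c(0, 6))
  expect_equal(flux_ratio(zero2, 6), 0)
  # choose df/dt so that v2(0) = (dCdt + vc) / 2, i.e. v1(0) = v2(0)
  # (v1 goes negative later on this grid, hence the warning)
  balanced <- suppressWarnings(
    compute_fluxes(pool, linear_trend(0.06, 0), 0.8, 10, grid = c(0, 6)))
  expect_equal(flux_ratio(balanced, 0), 1)
  none <- compute_fluxes(linear_trend(0, 100), linear_trend(0, 0.85),
                         0.85, 0, grid = 0)
  expect_error(flux_ratio(none, 0), class = "phepart_undefined_ratio")
  expect_equal(percent_change(10, 6.8), 32)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(10, 0), 100)
  expect_error(percent_change(0, 5), class = "phepart_zero_reference")
})
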