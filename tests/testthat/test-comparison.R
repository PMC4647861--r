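# Genotype contrasts: vc rescaling, Welch tests, trend tests, Bonferroni.

test_that("vc rescaling uses the mean emission fraction", {
  expect_equal(scale_consumption_rate(10, c(0.7, 0.6)), 6.5)
  expect_equal(scale_consumption_rate(8.2, 1), 8.2)
  expect_equal(scale_consumption_rate(10, rep(0.4, 3)), 4)
  # homogeneous of degree 1 in vc
  expect_equal(scale_consumption_rate(3 * 10, c(0.7, 0.6)),
               3 * scale_consumption_rate(10, c(0.7, 0.6)))
  expect_error(scale_consumption_rate(10, numeric(0)),
               class = "phepart_empty_fractions")
  expect_error(scale_consumption_rate(10, c(0.5, -1)),
               class = "phepart_bad_config")
})

test_that("identical groups give t = 0 and p = 1", {
  cmp <- compare_absolute_fluxes(c(10, 10, 10), c(10, 10, 10), m = 3)
  expect_equal(cmp$stat, 0)
  expect_equal(cmp$p_raw, 1)
  expect_equal(cmp$p_corrected, 1)
})

test_that("Welch test matches the hand formula and doubles under m = 2", {
  a <- c(12.5, 12.0, 13.0)
  b <- c(8.5, 8.0, 9.0)
  cmp <- compare_absolute_fluxes(a, b, m = 2)
  # hand Welch: se^2 = va/na + vb/nb, df by Welch-Satterthwaite
  va <- var(a); vb <- var(b)
  se2 <- va / 3 + vb / 3
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / 3)^2 / 2 + (vb / 3)^2 / 2)
  p <- 2 * pt(-abs(tstat), df)
  expect_equal(cmp$stat, tstat, tolerance = 1e-12)
  expect_equal(cmp$p_raw, p, tolerance = 1e-12)
  expect_equal(cmp$p_corrected, min(1, 2 * p))
})

test_that("separated groups reject as jitter shrinks", {
  for (jit in c(0.1, 0.01)) {
    set.seed(5)
    cmp <- compare_absolute_fluxes(10 + jit * rnorm(3), 8 + jit * rnorm(3),
                                   m = 2)
    if (jit == 0.01) expect_lt(cmp$p_corrected, 1e-4)
  }
  # degenerate separation: distinct constants
  cmp0 <- compare_absolute_fluxes(c(10, 10, 10), c(8, 8, 8))
  expect_equal(cmp0$p_raw, 0)
})

test_that("Bonferroni correction is monotone and capped at 1", {
  set.seed(8)
  a <- rnorm(4, 10); b <- rnorm(4, 10)
  for (m in c(1, 2, 10, 1000)) {
    cmp <- compare_absolute_fluxes(a, b, m = m)
    expect_gte(cmp$p_corrected, cmp$p_raw)
    expect_lte(cmp$p_corrected, 1)
  }
})

test_that("pooled mode uses a z statistic from propagated variances", {
  cmp <- compare_absolute_fluxes(12, 9, mode = "pooled",
                                 var_a = 1, var_b = 1, m = 1)
  z <- 3 / sqrt(2)
  expect_equal(cmp$stat, z)
  expect_equal(cmp$p_raw, 2 * pnorm(-z))
  expect_equal(cmp$mode, "pooled")
  expect_error(compare_absolute_fluxes(c(10, 11), c(9, 9.5, 10),
                                       mode = "replicate", m = 1),
               regexp = NA)
  expect_error(compare_absolute_fluxes(10, c(9, 9.5, 10)),
               class = "phepart_insufficient_replicates")
})

make_traj <- function(v2_level, v2_slope, grid = seq(0, 6, 0.5)) {
  # build a trajectory with prescribed v2 by choosing df/dt accordingly
  structure(list(grid = grid, v1 = 15 - (v2_level + v2_slope * grid),
                 v2 = v2_level + v2_slope * grid, vc = 10,
                 v1_variance = rep(0, length(grid)),
                 v2_variance = rep(0, length(grid)), vc_variance = 0,
                 f_tyr = 0.85, f_tyr_variance = 0, enrichment = "product",
                 pool_trend = NULL, frac_trend = NULL),
            class = "flux_trajectory")
}

test_that("trend comparison: identical and offset cases", {
  a <- make_traj(1, 0.2)
  # paired mode on identical trajectories
  cmp <- compare_flux_trends(a, a, mode = "paired_times")
  expect_equal(cmp$p_raw, 1)
  expect_equal(cmp$mode, "paired_times")
  # slopes mode: same slope, different levels -> p = 1
  grp_a <- list(make_traj(1, 0.2), make_traj(1.5, 0.2))
  grp_b <- list(make_traj(3, 0.2), make_traj(2, 0.2))
  cmp2 <- compare_flux_trends(grp_a, grp_b, mode = "slopes")
  expect_equal(cmp2$p_raw, 1)
  expect_equal(cmp2$mode, "slopes")
  # grid mismatch is an error
  expect_error(
    compare_flux_trends(a, make_traj(1, 0.2, grid = seq(0, 6, 0.25))),
    class = "phepart_grid_mismatch")
  expect_error(compare_flux_trends(list(a), list(a), mode = "slopes"),
               class = "phepart_insufficient_replicates")
})

test_that("slope test detects a doubled v2 trend in most noisy repeats", {
  # ground-truth v2 slopes 0.5 vs 1.0 per hour at replicate noise CV 5%
  ctrl <- flux_scenario(dfdt = 0.5 * 0.85 / 20, replicates = 3)
  hits <- 0L
  nrep <- 60
  for (k in seq_len(nrep)) {
    pair <- make_genotype_pair(ctrl, v1_scale = 1, v2_slope_scale = 2,
                               n_perturbed = 6, seed = 300 + k)
    fit <- suppressWarnings(phepart(pair$data))
    cmp <- compare_flux_trends(fit$trajectories$control,
                               fit$trajectories$perturbed, mode = "slopes")
    hits <- hits + (cmp$p_raw < 0.01 &&
                      cmp$estimate_b > cmp$estimate_a)
  }
  expect_gte(hits / nrep, 0.8)
})
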