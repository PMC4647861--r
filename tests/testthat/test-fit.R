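# The fitted model object and its methods.

noise_free_fit <- function() {
  pair <- make_genotype_pair(quiet_scenario(), seed = 21)
  suppressWarnings(phepart(pair$data))
}

test_that("fitting a null pair gives p = 1 and zero percent change", {
  fit <- noise_free_fit()
  expect_s3_class(fit, "phepart")
  expect_equal(fit$summary$pct_v1_t0[2], 0)
  expect_equal(fit$summary$pct_v1_tend[2], 0)
  cmp <- as.data.frame(fit$comparisons)
  expect_equal(cmp$p_corrected[cmp$quantity == "v1"], c(1, 1))
})

test_that("summary and print render without error and carry the numbers", {
  fit <- noise_free_fit()
  s <- summary(fit)
  expect_s3_class(s, "summary.phepart")
  out <- capture.output(print(s))
  expect_true(any(grepl("v2/v1", out)))
  out2 <- capture.output(print(fit))
  expect_true(any(grepl("control", out2)))
})

test_that("coef returns per-replicate trend estimates", {
  fit <- noise_free_fit()
  cf <- coef(fit)
  expect_equal(nrow(cf), 3 + 6)
  expect_named(cf, c("genotype", "replicate", "dCdt", "dCdt_se",
                     "dfdt", "dfdt_se", "f_tyr", "vc"))
  expect_equal(cf$dCdt, rep(5, 9))
  expect_equal(cf$f_tyr, rep(0.85, 9))
})

test_that("predict evaluates the closed-form fluxes at new times", {
  fit <- noise_free_fit()
  pr <- predict(fit, times = c(0, 1.5, 6), genotype = "control")
  truth <- truth_trajectory(quiet_scenario(), grid = c(0, 1.5, 6))
  expect_equal(pr$v1, truth$v1, tolerance = 1e-12)
  expect_equal(pr$v2, truth$v2, tolerance = 1e-12)
})

test_that("residuals are zero on noise-free data, non-zero with noise", {
  fit <- noise_free_fit()
  r <- residuals(fit)
  expect_equal(max(abs(r$residual)), 0)
  noisy <- make_genotype_pair(flux_scenario(), seed = 22)
  fit2 <- suppressWarnings(phepart(noisy$data))
  expect_gt(max(abs(residuals(fit2)$residual)), 0)
})

test_that("plot draws without error", {
  fit <- noise_free_fit()
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("simulate returns valid datasets and is seed-deterministic", {
  pair <- make_genotype_pair(flux_scenario(), seed = 23)
  fit <- suppressWarnings(phepart(pair$data))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  for (d in sims) {
    expect_s3_class(d, "labeling_data")
    expect_true(validate_labeling_data(as.data.frame(d)))
    expect_setequal(unique(d$genotype), c("control", "perturbed"))
  }
  sims2 <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(sims, sims2)
})

test_that("pooled fitting equals per-replicate fitting on identical replicates", {
  pair <- make_genotype_pair(quiet_scenario(), seed = 24)
  per <- suppressWarnings(phepart(pair$data))
  pooled <- suppressWarnings(
    phepart(pair$data, flux_config(pooling = "pooled")))
  expect_equal(pooled$summary$v1_t0, per$summary$v1_t0, tolerance = 1e-12)
  expect_equal(pooled$summary$v2_tend, per$summary$v2_tend,
               tolerance = 1e-12)
  expect_equal(as.data.frame(pooled$comparisons)$mode,
               c("pooled", "pooled", "paired_times"))
})

test_that("configured emission fractions rescale vc for the perturbed line", {
  pair <- make_genotype_pair(quiet_scenario(), vc_fraction = 0.65, seed = 25)
  cfg <- flux_config(rnai_emission_fractions = list(perturbed = c(0.7, 0.6)))
  fit <- suppressWarnings(phepart(pair$data, cfg))
  cf <- coef(fit)
  expect_equal(unique(cf$vc[cf$genotype == "perturbed"]), 0.65 * 10)
})

test_that("fit errors carry the stage and series identity", {
  pair <- make_genotype_pair(quiet_scenario(), seed = 26)
  df <- as.data.frame(pair$data)
  df <- df[!(df$genotype == "perturbed" & df$replicate == "r2" &
               df$variable == "frac_phe"), ]
  err <- tryCatch(phepart(labeling_data(df)), error = function(e) e)
  expect_s3_class(err, "phepart_lookup_error")
  expect_match(conditionMessage(err), "perturbed, r2")
  expect_error(phepart(pair$data, flux_config(control = "missing")),
               class = "phepart_lookup_error")
})
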