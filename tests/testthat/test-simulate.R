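# Synthetic-data generator: oracles, determinism, noise model.

test_that("noise-free exact-linear data round-trip the pipeline exactly", {
  # the module's central oracle: the estimator's assumptions are literally
  # true, so the fitted fluxes equal the generator's ground truth
  scn <- quiet_scenario(C0 = 100, dCdt = 5, f0 = 0, dfdt = 0.02,
                        f_tyr = 0.8, vc = 10, replicates = 2)
  sim <- simulate_exact_linear(scn)
  fit <- suppressWarnings(phepart(sim$data))
  for (r in names(fit$trajectories$control)) {
    tr <- fit$trajectories$control[[r]]
    expect_lt(max(abs(tr$v1 - sim$truth$v1) / abs(sim$truth$v1)), 1e-12)
    expect_lt(max(abs(tr$v2 - sim$truth$v2) / abs(sim$truth$v2)), 1e-12)
  }
  # the worked closed-form values
  n <- length(sim$truth$grid)
  expect_equal(sim$truth$v2[1], 2.5)
  expect_equal(sim$truth$v2[n], 5.5)
  expect_equal(sim$truth$v1[1], 12.5)
  expect_equal(sim$truth$v1[n], 9.5)
})

test_that("zero enrichment implies zero ground-truth v2", {
  scn <- quiet_scenario(f0 = 0, dfdt = 0)
  expect_equal(truth_trajectory(scn)$v2, rep(0, 61))
})

test_that("identical scenario and seed give identical dataset bytes", {
  scn <- flux_scenario(seed = 77, replicates = 3)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_labeling_data(simulate_exact_linear(scn)$data, f1)
  write_labeling_data(simulate_exact_linear(scn)$data, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed, different bytes
  scn$seed <- 78
  f3 <- withr::local_tempfile()
  write_labeling_data(simulate_exact_linear(scn)$data, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("infeasible scenarios are rejected before generation", {
  expect_error(flux_scenario(f0 = 0.9, dfdt = 0.05),
               class = "phepart_infeasible_scenario")
  expect_error(flux_scenario(C0 = 10, dCdt = -5),
               class = "phepart_infeasible_scenario")
  expect_error(flux_scenario(f_tyr = 0),
               class = "phepart_infeasible_scenario")
  expect_error(flux_scenario(times = c(0, 2)),
               class = "phepart_infeasible_scenario")
})

test_that("fraction clipping is counted and keeps values in [0, 1]", {
  scn <- flux_scenario(f0 = 0, dfdt = 0.001, noise_sd_frac = 0.3,
                       replicates = 5, seed = 12)
  sim <- simulate_exact_linear(scn)
  expect_gt(sim$n_clipped, 0)
  fr <- sim$data$value[sim$data$variable %in% c("frac_phe", "frac_tyr")]
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("RK4 integration matches the closed-form exponential solution", {
  # constant fluxes with v1 + v2 = vc keep the pool constant and give
  # f(t) = (v2 fTyr / vc) (1 - exp(-vc t / C0))
  scn <- flux_scenario(mode = "mechanistic", v1 = 7.5, v2 = 2.5, vc = 10,
                       C0 = 100, f0 = 0, f_tyr = 0.8,
                       f_tyr_plateau_time = 0, noise_cv_pool = 0,
                       noise_cv_emission = 0, noise_sd_frac = 0)
  sim <- simulate_mechanistic(scn)
  st <- sim$state(6)
  expect_equal(st$C, 100, tolerance = 1e-10)
  expect_lt(abs(st$f - 0.2 * (1 - exp(-0.6))), 1e-8)
  # no label source: f stays 0
  scn0 <- flux_scenario(mode = "mechanistic", v1 = 10, v2 = 0, vc = 10,
                        C0 = 100, f0 = 0, f_tyr = 0.8,
                        f_tyr_plateau_time = 0, noise_cv_pool = 0,
                        noise_cv_emission = 0, noise_sd_frac = 0)
  expect_equal(simulate_mechanistic(scn0)$state(6)$f, 0, tolerance = 1e-12)
  # steady pool for any v1 + v2 = vc split
  scn1 <- flux_scenario(mode = "mechanistic", v1 = 2, v2 = 8, vc = 10,
                        C0 = 80, f0 = 0, f_tyr = 0.9,
                        f_tyr_plateau_time = 0, noise_cv_pool = 0,
                        noise_cv_emission = 0, noise_sd_frac = 0)
  expect_equal(simulate_mechanistic(scn1)$state(4)$C, 80, tolerance = 1e-9)
})

test_that("an infeasible mechanistic scenario errors during integration", {
  scn <- flux_scenario(mode = "mechanistic", v1 = 0, v2 = 0, vc = 30,
                       C0 = 50, f0 = 0, f_tyr = 0.8,
                       noise_cv_pool = 0, noise_cv_emission = 0,
                       noise_sd_frac = 0)
  expect_error(simulate_mechanistic(scn),
               class = "phepart_infeasible_scenario")
})

test_that("identity perturbation reproduces the control ground truth", {
  pair <- make_genotype_pair(quiet_scenario(), seed = 5)
  expect_equal(pair$truth$control$v1, pair$truth$perturbed$v1)
  expect_equal(pair$truth$control$v2, pair$truth$perturbed$v2)
  expect_equal(pair$scenarios$perturbed$dCdt, pair$scenarios$control$dCdt)
  expect_equal(pair$scenarios$perturbed$dfdt, pair$scenarios$control$dfdt)
})

test_that("v1 scaling yields exact percent change through the pipeline", {
  pair <- make_genotype_pair(quiet_scenario(), v1_scale = 0.6, seed = 3)
  fit <- suppressWarnings(phepart(pair$data))
  expect_equal(fit$summary$pct_v1_t0[2], 40)
  expect_equal(fit$summary$pct_v1_tend[2], 40)
  # whole-trajectory property of the ground truth
  expect_equal(pair$truth$perturbed$v1, 0.6 * pair$truth$control$v1)
})

test_that("vc fraction scales the perturbed consumption rate by construction", {
  pair <- make_genotype_pair(quiet_scenario(), vc_fraction = 0.65, seed = 4)
  expect_equal(pair$truth$perturbed$vc, 0.65 * pair$truth$control$vc)
  pair2 <- make_genotype_pair(quiet_scenario(), vc_fraction = c(0.7, 0.6),
                              seed = 4)
  expect_equal(pair2$truth$perturbed$vc, 0.65 * pair2$truth$control$vc)
})

test_that("the knockdown emulation shows the expected flux pattern", {
  pair <- make_rnai_pair(quiet_scenario(), seed = 9)
  tr_c <- pair$truth$control
  tr_r <- pair$truth$rnai
  n <- length(tr_c$grid)
  expect_equal(percent_change(tr_c$v1[1], tr_r$v1[1]), 32)
  expect_gt(percent_change(tr_c$v1[n], tr_r$v1[n]), 40)
  expect_gt(tr_r$v2[n] / tr_r$v1[n], tr_c$v2[n] / tr_c$v1[n])
})
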