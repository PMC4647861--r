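# Shared fixture builders; everything is generated in code.

# A small well-formed long-format data frame (one pool series).
tiny_pool_df <- function(genotype = "control", replicate = "r1",
                         values = c(100, 110, 120, 130)) {
  data.frame(genotype = genotype, replicate = replicate,
             time_h = c(0, 2, 4, 6), variable = "pool_phe",
             value = values, stringsAsFactors = FALSE)
}

# Noise-free default control scenario.
quiet_scenario <- function(...) {
  flux_scenario(noise_cv_pool = 0, noise_cv_emission = 0,
                noise_sd_frac = 0, ...)
}

# Random feasible exact-linear scenario with fluxes bounded away from zero
# (so relative errors are well defined); rejection-sampled, deterministic
# under the ambient RNG.
random_scenario <- function(replicates = 1, noise = FALSE) {
  repeat {
    scn <- try(flux_scenario(
      C0 = runif(1, 50, 150), dCdt = runif(1, 1, 8),
      f0 = runif(1, 0, 0.02), dfdt = runif(1, 0.003, 0.02),
      f_tyr = runif(1, 0.7, 0.95), vc = runif(1, 3, 20),
      noise_cv_pool = if (noise) 0.05 else 0,
      noise_cv_emission = if (noise) 0.05 else 0,
      noise_sd_frac = if (noise) 0.01 else 0,
      replicates = replicates), silent = TRUE)
    if (inherits(scn, "try-error")) next
    tr <- truth_trajectory(scn, grid = c(0, 6))
    if (min(tr$v1) > 0.5 && min(tr$v2) > 0.05) return(scn)
  }
}

# Per-replicate v1/v2 values at a grid index, from a fitted model.
replicate_flux_at <- function(fit, genotype, component, index) {
  vapply(fit$trajectories[[genotype]], function(tr) tr[[component]][index],
         numeric(1))
}
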