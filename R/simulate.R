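# Synthetic labelling-data generator with known ground-truth fluxes.
#
# Two generating modes:
#  * exact_linear -- the estimator's own assumptions are literally true:
#    C(t) and f(t) affine, fTyr constant, cumulative emission vc*t. The
#    implied ground-truth fluxes follow from the mass balances, so the
#    full pipeline must recover them exactly on noise-free data.
#  * mechanistic -- fluxes v1(t), v2(t) are prescribed affine functions and
#    the two mass balances are integrated forward (fixed-step RK4), so the
#    observables are only approximately linear; this probes the linear
#    approximation.
# Noise: multiplicative Gaussian (CV) on concentration-like variables
# (pool, emission), additive Gaussian on fractions with clipping to [0, 1]
# (clipping events are counted and reported on the result).

#' Define a synthetic labelling scenario
#'
#' The defaults describe the study conditions the package emulates: a
#' control petunia flower fed 15N-tyrosine at t = 0, sampled at 0/2/4/6 h,
#' with tyrosine labelling holding a pseudo-steady plateau of 0.85
#' (reached within 2 h, so the 2/4/6-h samples see only the plateau), a
#' linearly growing phenylalanine pool (100 + 5 t nmol/gFW), linearly
#' rising phenylalanine labelling (0.009/h from 0) and a constant
#' consumption rate of 10 nmol/gFW/h -- numbers chosen so the control
#' cytosolic/plastidial flux ratio at 6 h is about 0.18, a minor cytosolic
#' contribution. Replicate noise defaults: CV 5% on pools and emission,
#' s.d. 0.01 on fractions.
#'
#' @param mode `"exact_linear"` or `"mechanistic"`.
#' @param C0 initial phenylalanine pool, nmol/gFW.
#' @param dCdt pool slope, nmol/gFW/h (exact-linear mode).
#' @param f0 initial phenylalanine labelling fraction.
#' @param dfdt labelling-fraction slope, 1/h (exact-linear mode).
#' @param f_tyr tyrosine labelling plateau, in (0, 1].
#' @param vc consumption rate, nmol/gFW/h.
#' @param v1,v2 mechanistic mode only: affine flux functions as
#'   `c(level, slope)` (a single number means a constant flux),
#'   nmol/gFW/h and nmol/gFW/h^2.
#' @param f_tyr_plateau_time mechanistic mode: hours over which tyrosine
#'   labelling rises linearly from 0 to the plateau (0 = constant from the
#'   start; default 2 h, matching the observed rapid rise -- the default
#'   sampling times see only the plateau).
#' @param noise_cv_pool,noise_cv_emission coefficient of variation of the
#'   multiplicative noise on pool / emission observations.
#' @param noise_sd_frac absolute s.d. of the additive noise on fraction
#'   observations (clipped to `[0, 1]`).
#' @param replicates biological replicates to generate.
#' @param times sampling times in hours; must contain 0 (the measured
#'   intercepts) and at least two later points.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return A `flux_scenario` object.
#' @export
flux_scenario <- function(mode = c("exact_linear", "mechanistic"),
                          C0 = 100, dCdt = 5, f0 = 0, dfdt = 0.009,
                          f_tyr = 0.85, vc = 10,
                          v1 = NULL, v2 = NULL, f_tyr_plateau_time = 2,
                          noise_cv_pool = 0.05, noise_cv_emission = 0.05,
                          noise_sd_frac = 0.01,
                          replicates = 3, times = c(0, 2, 4, 6),
                          seed = NULL) {
  mode <- match.arg(mode)
  pf_check_numeric(times, "times")
  if (!0 %in% times || sum(times > 0) < 2) {
    pf_stop("phepart_infeasible_scenario",
            "times must include 0 and at least two post-feeding points")
  }
  if (any(times < 0)) {
    pf_stop("phepart_bad_time", "sampling times must be >= 0")
  }
  if (f_tyr <= 0 || f_tyr > 1) {
    pf_stop("phepart_infeasible_scenario", "f_tyr must lie in (0, 1]")
  }
  if (noise_cv_pool < 0 || noise_cv_emission < 0 || noise_sd_frac < 0) {
    pf_stop("phepart_bad_config", "noise parameters must be >= 0")
  }
  if (replicates < 1) {
    pf_stop("phepart_bad_config", "replicates must be >= 1")
  }
  if (vc < 0) pf_stop("phepart_negative_value", "vc must be >= 0")
  tmax <- max(times)
  affine <- function(x, name) {
    if (is.null(x)) {
      pf_stop("phepart_infeasible_scenario",
              sprintf("mechanistic mode requires '%s'", name))
    }
    pf_check_numeric(x, name)
    if (length(x) == 1) x <- c(x, 0)
    if (length(x) != 2) {
      pf_stop("phepart_bad_config",
              sprintf("'%s' must be c(level, slope) or a constant", name))
    }
    x
  }
  if (mode == "exact_linear") {
    fr <- f0 + dfdt * c(0, tmax)
    if (any(fr < 0 | fr > 1)) {
      pf_stop("phepart_infeasible_scenario",
              "f(t) leaves [0, 1] within the sampling horizon")
    }
    if (any(C0 + dCdt * c(0, tmax) <= 0)) {
      pf_stop("phepart_infeasible_scenario",
              "C(t) must stay positive over the sampling horizon")
    }
    v1 <- v2 <- NULL
  } else {
    v1 <- affine(v1, "v1")
    v2 <- affine(v2, "v2")
  }
  structure(list(mode = mode, C0 = C0, dCdt = dCdt, f0 = f0, dfdt = dfdt,
                 f_tyr = f_tyr, vc = vc, v1 = v1, v2 = v2,
                 f_tyr_plateau_time = f_tyr_plateau_time,
                 noise_cv_pool = noise_cv_pool,
                 noise_cv_emission = noise_cv_emission,
                 noise_sd_frac = noise_sd_frac,
                 replicates = replicates, times = sort(times), seed = seed),
            class = "flux_scenario")
}

#' @export
print.flux_scenario <- function(x, ...) {
  cat(sprintf("<flux_scenario> mode: %s, %d replicate(s), times %s h\n",
              x$mode, x$replicates, paste(x$times, collapse = "/")))
  if (x$mode == "exact_linear") {
    cat(sprintf("  C(t) = %g + %g t, f(t) = %g + %g t, fTyr = %g, vc = %g\n",
                x$C0, x$dCdt, x$f0, x$dfdt, x$f_tyr, x$vc))
  } else {
    cat(sprintf("  v1(t) = %g + %g t, v2(t) = %g + %g t, vc = %g\n",
                x$v1[1], x$v1[2], x$v2[1], x$v2[2], x$vc))
  }
  invisible(x)
}

# Tyrosine labelling profile of a scenario at times t.
pf_ftyr_profile <- function(scenario, t) {
  pt <- scenario$f_tyr_plateau_time
  if (scenario$mode == "exact_linear" || pt <= 0) {
    rep(scenario$f_tyr, length(t))
  } else {
    scenario$f_tyr * pmin(t / pt, 1)
  }
}

#' Ground-truth flux trajectory implied by a scenario
#'
#' For an exact-linear scenario the true fluxes follow from the mass
#' balances applied to the generating affine trends; for a mechanistic
#' scenario they are the prescribed affine flux functions themselves.
#'
#' @param scenario a [flux_scenario()].
#' @param grid evaluation times, hours.
#' @return A `flux_trajectory` with zero variances.
#' @export
truth_trajectory <- function(scenario, grid = seq(0, 6, by = 0.1)) {
  stopifnot(inherits(scenario, "flux_scenario"))
  if (scenario$mode == "exact_linear") {
    compute_fluxes(linear_trend(scenario$dCdt, scenario$C0),
                   linear_trend(scenario$dfdt, scenario$f0),
                   f_tyr = scenario$f_tyr, vc = scenario$vc, grid = grid,
                   enrichment = "product")
  } else {
    v1 <- scenario$v1[1] + scenario$v1[2] * grid
    v2 <- scenario$v2[1] + scenario$v2[2] * grid
    structure(list(grid = grid, v1 = v1, v2 = v2, vc = scenario$vc,
                   v1_variance = rep(0, length(grid)),
                   v2_variance = rep(0, length(grid)),
                   vc_variance = 0, f_tyr = scenario$f_tyr,
                   f_tyr_variance = 0, enrichment = "product",
                   pool_trend = NULL, frac_trend = NULL),
              class = "flux_trajectory")
  }
}

# Assemble one genotype's noisy observations given noise-free values.
# Returns a data frame plus the number of clipped fraction observations.
pf_observe <- function(scenario, genotype, C_true, f_true, fT_true,
                       em_true) {
  times <- scenario$times
  tpos <- times[times > 0]
  n_clipped <- 0L
  rows <- vector("list", scenario$replicates)
  for (i in seq_len(scenario$replicates)) {
    rep_id <- sprintf("r%d", i)
    mul <- function(v, cv) {
      if (cv > 0) pmax(v * (1 + cv * stats::rnorm(length(v))), 0) else v
    }
    addf <- function(v, sd) {
      if (sd > 0) {
        out <- v + sd * stats::rnorm(length(v))
        n_clipped <<- n_clipped + sum(out < 0 | out > 1)
        pmin(pmax(out, 0), 1)
      } else v
    }
    pool <- mul(C_true, scenario$noise_cv_pool)
    frac <- addf(f_true, scenario$noise_sd_frac)
    ftyr <- addf(fT_true, scenario$noise_sd_frac)
    em <- mul(em_true, scenario$noise_cv_emission)
    rows[[i]] <- data.frame(
      genotype = genotype, replicate = rep_id,
      time_h = c(times, times, tpos, times),
      variable = c(rep("pool_phe", length(times)),
                   rep("frac_phe", length(times)),
                   rep("frac_tyr", length(tpos)),
                   rep("emission_total", length(times))),
      value = c(pool, frac, ftyr, em),
      stringsAsFactors = FALSE)
  }
  list(df = do.call(rbind, rows), n_clipped = n_clipped)
}

#' Simulate a dataset whose observables are exactly affine
#'
#' The generating model is the analysis model's own assumption set:
#' `C(t) = C0 + dCdt t`, `f(t) = f0 + dfdt t`, constant tyrosine
#' labelling, cumulative emission `vc t`. With zero noise the full
#' pipeline recovers the implied ground-truth fluxes exactly (the
#' package's central oracle). Deterministic given the scenario seed.
#'
#' @param scenario an exact-linear [flux_scenario()].
#' @param genotype genotype label for the generated series.
#' @return List with `data` (a [labeling_data()]), `truth` (the
#'   ground-truth `flux_trajectory` on a 6-min grid over the sampling
#'   horizon), `scenario`, and `n_clipped` (fraction observations clipped
#'   to `[0, 1]`).
#' @export
simulate_exact_linear <- function(scenario, genotype = "control") {
  stopifnot(inherits(scenario, "flux_scenario"))
  if (scenario$mode != "exact_linear") {
    pf_stop("phepart_bad_config", "scenario mode must be 'exact_linear'")
  }
  times <- scenario$times
  tpos <- times[times > 0]
  C_true <- scenario$C0 + scenario$dCdt * times
  f_true <- scenario$f0 + scenario$dfdt * times
  fT_true <- pf_ftyr_profile(scenario, tpos)
  em_true <- scenario$vc * times
  obs <- pf_with_seed(scenario$seed,
                      pf_observe(scenario, genotype, C_true, f_true,
                                 fT_true, em_true))
  grid <- seq(0, max(times), by = 0.1)
  list(data = labeling_data(obs$df),
       truth = truth_trajectory(scenario, grid),
       scenario = scenario, n_clipped = obs$n_clipped)
}

#' Simulate a dataset by integrating the mass balances forward
#'
#' Prescribed affine fluxes `v1(t)`, `v2(t)` and constant `vc` drive the
#' pool and labelled-pool balances
#' `dC/dt = v1 + v2 - vc` and `d(f C)/dt = v2 fTyr(t) - vc f`,
#' integrated with a fixed-step fourth-order Runge-Kutta scheme
#' (step 0.0025 h) via \pkg{deSolve}. Sampling and noise as in
#' [simulate_exact_linear()].
#'
#' @param scenario a mechanistic [flux_scenario()].
#' @param genotype genotype label.
#' @param step integration step in hours (`<= 0.01`).
#' @return List with `data`, `truth` (prescribed fluxes on a 6-min grid),
#'   `scenario`, `n_clipped`, and `state`, a function of time returning
#'   the noise-free `C` and `f` (interpolated from the integration grid).
#' @export
simulate_mechanistic <- function(scenario, genotype = "control",
                                 step = 0.0025) {
  stopifnot(inherits(scenario, "flux_scenario"))
  if (scenario$mode != "mechanistic") {
    pf_stop("phepart_bad_config", "scenario mode must be 'mechanistic'")
  }
  if (step <= 0 || step > 0.01) {
    pf_stop("phepart_bad_config", "integration step must be in (0, 0.01]")
  }
  times <- scenario$times
  tmax <- max(times)
  ode_times <- sort(unique(c(seq(0, tmax, by = step), times)))
  v1f <- function(t) scenario$v1[1] + scenario$v1[2] * t
  v2f <- function(t) scenario$v2[1] + scenario$v2[2] * t
  deriv <- function(t, y, parms) {
    f <- y[["L"]] / y[["C"]]
    list(c(C = v1f(t) + v2f(t) - scenario$vc,
           L = v2f(t) * pf_ftyr_profile(scenario, t) - scenario$vc * f))
  }
  sol <- deSolve::ode(y = c(C = scenario$C0, L = scenario$f0 * scenario$C0),
                      times = ode_times, func = deriv, parms = NULL,
                      method = "rk4")
  Cs <- sol[, "C"]
  if (any(!is.finite(Cs)) || any(Cs <= 0)) {
    pf_stop("phepart_infeasible_scenario",
            "pool size C(t) left the positive domain during integration")
  }
  fs <- sol[, "L"] / Cs
  idx <- match(times, ode_times)
  C_true <- Cs[idx]
  f_true <- fs[idx]
  tpos <- times[times > 0]
  fT_true <- pf_ftyr_profile(scenario, tpos)
  em_true <- scenario$vc * times
  obs <- pf_with_seed(scenario$seed,
                      pf_observe(scenario, genotype, C_true, f_true,
                                 fT_true, em_true))
  grid <- seq(0, tmax, by = 0.1)
  state <- function(t) {
    list(C = stats::approx(ode_times, Cs, t)$y,
         f = stats::approx(ode_times, fs, t)$y)
  }
  list(data = labeling_data(obs$df),
       truth = truth_trajectory(scenario, grid),
       scenario = scenario, n_clipped = obs$n_clipped, state = state)
}

#' Generate a two-genotype dataset (control and perturbed)
#'
#' Emulates the transporter-knockdown experiment: a perturbed genotype
#' with a lowered plastidial flux `v1`, optionally a steeper cytosolic
#' `v2` trend, and a consumption rate scaled by the perturbed lines'
#' emission fraction of control. Both genotypes are generated from one
#' shared seeded stream.
#'
#' Perturbations are expressed inside the linear-consistent observable
#' family (affine pool and labelling, constant tyrosine labelling), so
#' the implied ground-truth fluxes are exactly what the pipeline can
#' recover. With `v1_scale = s` alone, the whole plastidial trajectory is
#' rescaled (`v1'(t) = s v1(t)`) and the noise-free pipeline returns
#' [percent_change()] of exactly `100 (1 - s)` at every matched time. An
#' independent `v2_slope_scale` additionally steepens the cytosolic
#' trend; linear consistency then forces the v1 slope to `-1` times the
#' new v2 slope, so `v1_scale` applies at t = 0 and the endpoint
#' reduction follows from the steeper trend. In both cases the initial
#' phenylalanine labelling is kept at the control's (natural abundance)
#' and the v2 level is solved from linear consistency.
#'
#' @param control an exact-linear [flux_scenario()] for the control.
#' @param v1_scale scalar factor on the plastidial flux level.
#' @param v2_slope_scale factor on the v2 slope; `NULL` keeps the
#'   coupling implied by `v1_scale`.
#' @param vc_fraction per-line emission fractions of control (their mean
#'   scales `vc`), as in [scale_consumption_rate()].
#' @param n_control,n_perturbed replicates per genotype (defaults: the
#'   control scenario's count, and 6).
#' @param genotypes length-2 labels.
#' @param seed seed for the shared generation stream.
#' @return List with `data` (combined [labeling_data()]), `truth` (list
#'   of ground-truth trajectories per genotype), `scenarios`, and
#'   `perturbation`.
#' @export
make_genotype_pair <- function(control, v1_scale = 1, v2_slope_scale = NULL,
                               vc_fraction = 1,
                               n_control = NULL, n_perturbed = 6,
                               genotypes = c("control", "perturbed"),
                               seed = NULL) {
  stopifnot(inherits(control, "flux_scenario"))
  if (control$mode != "exact_linear") {
    pf_stop("phepart_bad_config",
            "the control scenario must be exact_linear")
  }
  if (length(v1_scale) != 1 || v1_scale <= 0) {
    pf_stop("phepart_bad_config", "v1_scale must be a positive scalar")
  }
  n_control <- n_control %||% control$replicates
  fT <- control$f_tyr
  # control flux system implied by the affine observables
  a2 <- (control$f0 * control$dCdt + control$C0 * control$dfdt +
           control$vc * control$f0) / fT
  b2 <- control$dfdt * (2 * control$dCdt + control$vc) / fT
  a1 <- control$dCdt + control$vc - a2
  vc_p <- control$vc * mean(vc_fraction)
  s <- v1_scale
  base <- control
  base$replicates <- n_control
  base$seed <- NULL
  # Targets in flux space: v1'(0) = s a1 and v2 slope b2' = r b2 (linear
  # consistency forces the v1 slope to -b2'). The initial phenylalanine
  # labelling f0 is kept at the control's (natural abundance) and the v2
  # level floats. With
  #   bf (2 dCdt' + vc') = b2' fT                      (v2 slope)
  #   a2' = (f0 (dCdt' + vc') + C0 bf) / fT            (v2 level implied)
  #   dCdt' + vc' - a2' = s a1                         (v1 level target)
  # elimination gives a quadratic in the labelling slope bf (positive
  # root taken).
  b2p <- (v2_slope_scale %||% v1_scale) * b2
  f0_p <- control$f0
  k <- 1 - f0_p / fT
  if (abs(k) < 1e-12) {
    pf_stop("phepart_infeasible_scenario",
            "control labelling already at the tyrosine plateau")
  }
  A <- 2 * control$C0 / (fT * k)
  D <- 2 * (s * a1 - vc_p + f0_p * vc_p / fT) / k + vc_p
  disc <- D^2 + 4 * A * b2p * fT
  if (disc < 0) {
    pf_stop("phepart_infeasible_scenario",
            "perturbation puts the labelling slope out of reach")
  }
  bf_p <- (-D + sqrt(disc)) / (2 * A)
  dCdt_p <- (s * a1 - vc_p + f0_p * vc_p / fT + control$C0 * bf_p / fT) / k
  perturbed <- flux_scenario(
    mode = "exact_linear", C0 = control$C0, dCdt = dCdt_p,
    f0 = f0_p, dfdt = bf_p, f_tyr = fT, vc = vc_p,
    noise_cv_pool = control$noise_cv_pool,
    noise_cv_emission = control$noise_cv_emission,
    noise_sd_frac = control$noise_sd_frac,
    replicates = n_perturbed, times = control$times, seed = NULL)
  sims <- pf_with_seed(seed, {
    sim_c <- simulate_exact_linear(base, genotype = genotypes[1])
    sim_p <- simulate_exact_linear(perturbed, genotype = genotypes[2])
    list(c = sim_c, p = sim_p)
  })
  data <- labeling_data(rbind(as.data.frame(sims$c$data),
                              as.data.frame(sims$p$data)))
  truth <- list(sims$c$truth, sims$p$truth)
  names(truth) <- genotypes
  scenarios <- list(base, perturbed)
  names(scenarios) <- genotypes
  list(data = data, truth = truth, scenarios = scenarios,
       perturbation = list(v1_scale = v1_scale,
                           v2_slope_scale = v2_slope_scale,
                           vc_fraction = vc_fraction),
       n_clipped = sims$c$n_clipped + sims$p$n_clipped)
}

#' Default transporter-knockdown scenario pair
#'
#' Convenience wrapper around [make_genotype_pair()] with the perturbation
#' the package uses to emulate an export-impaired (RNAi) genotype: the
#' plastidial flux v1 reduced to 68% of control at t0, a 1.665-fold
#' steeper cytosolic v2 trend, and vc scaled by emission fractions 0.7
#' and 0.6 (mean 0.65). Under the default control scenario the implied
#' ground truth has v1 32% lower at t0 and about 42% lower at t6 than
#' control, and a clearly larger v2/v1 ratio at t6 (about 0.57 versus
#' 0.18).
#'
#' @param control control scenario (default [flux_scenario()]).
#' @param seed seed for the generation stream.
#' @param ... further arguments passed to [make_genotype_pair()].
#' @return See [make_genotype_pair()].
#' @export
make_rnai_pair <- function(control = flux_scenario(), seed = NULL, ...) {
  make_genotype_pair(control, v1_scale = 0.68,
                     v2_slope_scale = 1.665, vc_fraction = c(0.7, 0.6),
                     genotypes = c("control", "rnai"), seed = seed, ...)
}
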