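# The main model fit: trends -> consumption rate -> fluxes -> variances ->
# summaries -> genotype comparisons.

# Fit the per-series trends of one (genotype, replicate).
pf_fit_replicate <- function(data, g, r, config) {
  pool <- extract_series(data, g, r, "pool_phe")
  frac <- extract_series(data, g, r, "frac_phe")
  tyr <- extract_series(data, g, r, "frac_tyr", require_intercept = FALSE)
  list(pool = pool, frac = frac,
       pool_trend = fit_fixed_intercept_slope(pool$times, pool$values,
                                              pool$intercept),
       frac_trend = fit_fixed_intercept_slope(frac$times, frac$values,
                                              frac$intercept),
       f_tyr = mean_tyrosine_labelling(tyr$values))
}

pf_has_series <- function(data, g, r, variable) {
  any(data$genotype == g & data$replicate == r & data$variable == variable)
}

pf_fit_emission <- function(data, g, r, config) {
  em <- extract_series(data, g, r, "emission_total",
                       require_intercept = FALSE)
  estimate_consumption_rate(em$times, em$values,
                            strict = config$strict_emission)
}

# Emission fractions configured for genotype g (NULL if none).
pf_genotype_fractions <- function(config, g) {
  fr <- config$rnai_emission_fractions
  if (is.null(fr)) return(NULL)
  if (is.numeric(fr)) return(fr)
  fr[[g]]
}

#' Fit the phenylalanine flux-partitioning model
#'
#' The central fitting function. For every genotype and biological
#' replicate it fits fixed-intercept linear trends to the phenylalanine
#' pool and its 15N labelling fraction, averages the tyrosine labelling
#' plateau, estimates the consumption rate \eqn{v_c} from cumulative
#' volatile emission (control), rescales \eqn{v_c} for perturbed
#' genotypes when emission fractions are configured, inverts the mass
#' balances to obtain the plastidial flux `v1` and cytosolic flux `v2` on
#' the evaluation grid with delta-method variances, and compares every
#' non-control genotype against control (Welch t-tests on absolute fluxes
#' at the grid endpoints, Bonferroni-corrected, plus a test on the v2
#' trend slopes).
#'
#' Genotype-mean fluxes are reported with propagated standard errors
#' (`sqrt(sum(Var_i)) / n` over replicates), consistent with the
#' delta-method treatment of each replicate's uncertainty.
#'
#' @param data a [labeling_data()] object or a path to its TSV form.
#' @param config a [flux_config()].
#' @return A `phepart` object with components `fits` (per
#'   genotype/replicate trends), `trajectories` (per-replicate
#'   `flux_trajectory` lists), `genotype_means`, `summary` (per-genotype
#'   flux summary incl. v2/v1 ratios and percent changes vs control),
#'   `comparisons` (a `genotype_comparison` table) and the inputs.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`, `residuals`,
#'   `simulate`.
#' @seealso [run_pipeline()] for the file-in/file-out wrapper.
#' @export
#' @examples
#' sim <- make_genotype_pair(flux_scenario(seed = NULL), seed = 1)
#' fit <- phepart(sim$data)
#' summary(fit)
phepart <- function(data, config = flux_config()) {
  if (is.character(data)) data <- read_labeling_data(data, config)
  stopifnot(inherits(data, "labeling_data"), inherits(config, "flux_config"))
  grid <- seq(config$grid_start, config$grid_end, by = config$grid_step)
  genotypes <- unique(data$genotype)
  control <- config$control %||%
    (if ("control" %in% genotypes) "control" else genotypes[1])
  if (!control %in% genotypes) {
    pf_stop("phepart_lookup_error",
            sprintf("control genotype '%s' not present in the data",
                    control))
  }
  genotypes <- c(control, setdiff(genotypes, control))
  if (config$pooling == "pooled") {
    return(pf_fit_pooled(data, config, grid, genotypes, control))
  }

  # --- per-replicate trends ------------------------------------------------
  fits <- list()
  for (g in genotypes) {
    reps <- unique(data$replicate[data$genotype == g])
    fits[[g]] <- lapply(stats::setNames(reps, reps), function(r) {
      tryCatch(pf_fit_replicate(data, g, r, config),
               phepart_error = function(e) {
                 pf_stop(class(e)[1], sprintf(
                   "stage trend_estimation, series (%s, %s): %s",
                   g, r, conditionMessage(e)))
               })
    })
  }

  # --- consumption rate ----------------------------------------------------
  ctrl_reps <- names(fits[[control]])
  vc_ctrl <- lapply(ctrl_reps, function(r) {
    if (!pf_has_series(data, control, r, "emission_total")) {
      pf_stop("phepart_lookup_error", sprintf(
        "stage consumption_rate: control replicate %s has no emission series",
        r))
    }
    pf_fit_emission(data, control, r, config)
  })
  names(vc_ctrl) <- ctrl_reps
  nc <- length(vc_ctrl)
  vc_ctrl_mean <- mean(vapply(vc_ctrl, `[[`, numeric(1), "slope"))
  vc_ctrl_mean_var <- sum(vapply(vc_ctrl, `[[`, numeric(1),
                                 "slope_variance")) / nc^2

  vc_for <- function(g, r) {
    if (g == control) return(vc_ctrl[[r]])
    fr <- pf_genotype_fractions(config, g)
    if (!is.null(fr)) {
      list(value = scale_consumption_rate(vc_ctrl_mean, fr),
           variance = vc_ctrl_mean_var * mean(fr)^2)
    } else if (pf_has_series(data, g, r, "emission_total")) {
      pf_fit_emission(data, g, r, config)
    } else {
      pf_stop("phepart_lookup_error", sprintf(
        paste0("stage consumption_rate, series (%s, %s): no emission data ",
               "and no configured emission fraction"), g, r))
    }
  }

  # --- fluxes --------------------------------------------------------------
  trajectories <- list()
  for (g in genotypes) {
    trajectories[[g]] <- lapply(stats::setNames(names(fits[[g]]),
                                                names(fits[[g]])),
                                function(r) {
      ft <- fits[[g]][[r]]
      compute_fluxes(ft$pool_trend, ft$frac_trend, ft$f_tyr, vc_for(g, r),
                     grid = grid, enrichment = config$enrichment_rate,
                     include_ftyr_variance = config$include_ftyr_variance,
                     include_intercept_variance =
                       config$include_intercept_variance)
    })
  }

  # --- genotype means with propagated SEs ----------------------------------
  genotype_means <- lapply(trajectories, function(trs) {
    n <- length(trs)
    v1m <- vapply(trs, `[[`, numeric(length(grid)), "v1")
    v2m <- vapply(trs, `[[`, numeric(length(grid)), "v2")
    v1v <- vapply(trs, `[[`, numeric(length(grid)), "v1_variance")
    v2v <- vapply(trs, `[[`, numeric(length(grid)), "v2_variance")
    if (length(grid) == 1) {
      v1m <- matrix(v1m, 1); v2m <- matrix(v2m, 1)
      v1v <- matrix(v1v, 1); v2v <- matrix(v2v, 1)
    }
    list(grid = grid, n = n,
         v1 = rowMeans(v1m), v2 = rowMeans(v2m),
         v1_se = sqrt(rowSums(v1v)) / n, v2_se = sqrt(rowSums(v2v)) / n,
         v1_sd = apply(v1m, 1, stats::sd), v2_sd = apply(v2m, 1, stats::sd),
         vc = mean(vapply(trs, `[[`, numeric(1), "vc")))
  })

  pf_assemble(data, config, grid, genotypes, control, fits, trajectories,
              genotype_means, vc_ctrl_mean, vc_ctrl_mean_var)
}

# Shared tail of the fit: summaries + comparisons + object assembly.
pf_assemble <- function(data, config, grid, genotypes, control, fits,
                        trajectories, genotype_means, vc_ctrl_mean,
                        vc_ctrl_mean_var) {
  iend <- length(grid)
  gm <- genotype_means
  summary_df <- do.call(rbind, lapply(genotypes, function(g) {
    m <- gm[[g]]
    ctrl <- gm[[control]]
    data.frame(
      genotype = g, n = m$n,
      v1_t0 = m$v1[1], v1_t0_se = m$v1_se[1],
      v1_tend = m$v1[iend], v1_tend_se = m$v1_se[iend],
      v2_t0 = m$v2[1], v2_t0_se = m$v2_se[1],
      v2_tend = m$v2[iend], v2_tend_se = m$v2_se[iend],
      vc = m$vc,
      ratio_tend = m$v2[iend] / m$v1[iend],
      pct_v1_t0 = if (g == control) 0 else
        percent_change(ctrl$v1[1], m$v1[1]),
      pct_v1_tend = if (g == control) 0 else
        percent_change(ctrl$v1[iend], m$v1[iend]),
      stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL

  comparisons <- NULL
  others <- setdiff(genotypes, control)
  replicate_mode <- config$pooling == "replicate"
  for (g in others) {
    m <- config$bonferroni_m %||% 2
    rows <- lapply(c(1, iend), function(i) {
      if (replicate_mode) {
        va <- vapply(trajectories[[control]], function(tr) tr$v1[i],
                     numeric(1))
        vb <- vapply(trajectories[[g]], function(tr) tr$v1[i], numeric(1))
        compare_absolute_fluxes(va, vb, m = m, labels = c(control, g),
                                quantity = "v1", time_h = grid[i])
      } else {
        compare_absolute_fluxes(
          gm[[control]]$v1[i], gm[[g]]$v1[i], m = m, mode = "pooled",
          var_a = gm[[control]]$v1_se[i]^2, var_b = gm[[g]]$v1_se[i]^2,
          labels = c(control, g), quantity = "v1", time_h = grid[i])
      }
    })
    trend_row <- if (replicate_mode) {
      compare_flux_trends(trajectories[[control]], trajectories[[g]],
                          mode = "slopes", component = "v2",
                          labels = c(control, g))
    } else {
      compare_flux_trends(trajectories[[control]][[1]],
                          trajectories[[g]][[1]],
                          mode = "paired_times", component = "v2",
                          labels = c(control, g))
    }
    comparisons <- rbind(comparisons, do.call(rbind, rows), trend_row)
  }
  if (!is.null(comparisons)) {
    class(comparisons) <- c("genotype_comparison", "data.frame")
  }

  structure(list(data = data, config = config, grid = grid,
                 genotypes = genotypes, control = control,
                 fits = fits, trajectories = trajectories,
                 genotype_means = genotype_means,
                 vc_control = list(value = vc_ctrl_mean,
                                   variance = vc_ctrl_mean_var),
                 summary = summary_df, comparisons = comparisons,
                 call = sys.call(-1)),
            class = "phepart")
}

# Pooled fitting: one trend per genotype from all replicates jointly.
pf_fit_pooled <- function(data, config, grid, genotypes, control) {
  fits <- list()
  for (g in genotypes) {
    reps <- unique(data$replicate[data$genotype == g])
    series <- lapply(reps, function(r) pf_fit_replicate(data, g, r, config))
    pool_t <- unlist(lapply(series, function(s) s$pool$times))
    pool_v <- unlist(lapply(series, function(s) s$pool$values))
    pool_i <- mean(vapply(series, function(s) s$pool$intercept, numeric(1)))
    frac_t <- unlist(lapply(series, function(s) s$frac$times))
    frac_v <- unlist(lapply(series, function(s) s$frac$values))
    frac_i <- mean(vapply(series, function(s) s$frac$intercept, numeric(1)))
    tyr_all <- unlist(lapply(reps, function(r) {
      extract_series(data, g, r, "frac_tyr", require_intercept = FALSE)$values
    }))
    fits[[g]] <- list(
      replicates = reps,
      pool_trend = fit_fixed_intercept_slope(pool_t, pool_v, pool_i),
      frac_trend = fit_fixed_intercept_slope(frac_t, frac_v, frac_i),
      f_tyr = mean_tyrosine_labelling(tyr_all))
  }
  ctrl_reps <- fits[[control]]$replicates
  em_t <- em_v <- numeric(0)
  for (r in ctrl_reps) {
    em <- extract_series(data, control, r, "emission_total",
                         require_intercept = FALSE)
    em_t <- c(em_t, em$times); em_v <- c(em_v, em$values)
  }
  vc_ctrl <- estimate_consumption_rate(em_t, em_v,
                                       strict = config$strict_emission)
  trajectories <- list()
  for (g in genotypes) {
    vc_g <- if (g == control) {
      vc_ctrl
    } else {
      fr <- pf_genotype_fractions(config, g)
      if (!is.null(fr)) {
        list(value = scale_consumption_rate(vc_ctrl$slope, fr),
             variance = vc_ctrl$slope_variance * mean(fr)^2)
      } else {
        em_t <- em_v <- numeric(0)
        for (r in fits[[g]]$replicates) {
          em <- extract_series(data, g, r, "emission_total",
                               require_intercept = FALSE)
          em_t <- c(em_t, em$times); em_v <- c(em_v, em$values)
        }
        estimate_consumption_rate(em_t, em_v,
                                  strict = config$strict_emission)
      }
    }
    trajectories[[g]] <- list(pooled = compute_fluxes(
      fits[[g]]$pool_trend, fits[[g]]$frac_trend, fits[[g]]$f_tyr, vc_g,
      grid = grid, enrichment = config$enrichment_rate,
      include_ftyr_variance = config$include_ftyr_variance,
      include_intercept_variance = config$include_intercept_variance))
  }
  genotype_means <- lapply(genotypes, function(g) {
    tr <- trajectories[[g]]$pooled
    list(grid = grid, n = length(fits[[g]]$replicates),
         v1 = tr$v1, v2 = tr$v2,
         v1_se = sqrt(tr$v1_variance), v2_se = sqrt(tr$v2_variance),
         v1_sd = rep(NA_real_, length(grid)),
         v2_sd = rep(NA_real_, length(grid)),
         vc = tr$vc)
  })
  names(genotype_means) <- genotypes
  pf_assemble(data, config, grid, genotypes, control, fits, trajectories,
              genotype_means, vc_ctrl$slope, vc_ctrl$slope_variance)
}
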