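# S3 methods for the fitted flux-partitioning model.

#' @export
print.phepart <- function(x, ...) {
  s <- x$summary
  iend <- length(x$grid)
  cat("Phenylalanine flux partitioning fit\n")
  cat(sprintf("  genotypes: %s (control: %s)\n",
              paste(sprintf("%s (n=%d)", s$genotype, s$n), collapse = ", "),
              x$control))
  cat(sprintf("  grid: %g to %g h, step %g h (%d points); fitting: %s\n",
              x$grid[1], x$grid[iend], x$config$grid_step, iend,
              x$config$pooling))
  cat(sprintf("  fluxes at t = %g h (nmol/gFW/h):\n", x$grid[iend]))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("    %-12s v1 = %7.3f  v2 = %7.3f  v2/v1 = %5.3f\n",
                s$genotype[i], s$v1_tend[i], s$v2_tend[i], s$ratio_tend[i]))
  }
  invisible(x)
}

#' Summarise a fitted flux-partitioning model
#'
#' @param object a `phepart` fit.
#' @param ... unused.
#' @return A `summary.phepart` object holding the per-genotype flux table
#'   (endpoint fluxes with propagated standard errors, v2/v1 ratios,
#'   percent changes of v1 relative to control) and the genotype
#'   comparison table.
#' @export
summary.phepart <- function(object, ...) {
  structure(list(summary = object$summary,
                 comparisons = object$comparisons,
                 control = object$control, grid = object$grid,
                 alpha = object$config$alpha,
                 pooling = object$config$pooling),
            class = "summary.phepart")
}

#' @export
print.summary.phepart <- function(x, ...) {
  iend <- length(x$grid)
  t0 <- x$grid[1]; tend <- x$grid[iend]
  cat(sprintf("Flux summary (control: %s; times t0 = %g h, t_end = %g h)\n",
              x$control, t0, tend))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s (n=%d):\n", s$genotype[i], s$n[i]))
    cat(sprintf("    v1: %7.3f +/- %.3f (t0)   %7.3f +/- %.3f (t_end)\n",
                s$v1_t0[i], s$v1_t0_se[i], s$v1_tend[i], s$v1_tend_se[i]))
    cat(sprintf("    v2: %7.3f +/- %.3f (t0)   %7.3f +/- %.3f (t_end)\n",
                s$v2_t0[i], s$v2_t0_se[i], s$v2_tend[i], s$v2_tend_se[i]))
    cat(sprintf("    vc: %7.3f    v2/v1 at t_end: %.3f\n",
                s$vc[i], s$ratio_tend[i]))
    if (s$genotype[i] != x$control) {
      cat(sprintf("    v1 vs control: %.1f%% lower (t0), %.1f%% lower (t_end)\n",
                  s$pct_v1_t0[i], s$pct_v1_tend[i]))
    }
  }
  if (!is.null(x$comparisons)) {
    cat(sprintf("Comparisons (Bonferroni-corrected, alpha = %g):\n",
                x$alpha))
    cmp <- as.data.frame(x$comparisons)
    for (i in seq_len(nrow(cmp))) {
      cat(sprintf("  %-22s %-10s %s p = %.4g%s\n",
                  cmp$comparison[i], cmp$quantity[i],
                  if (is.na(cmp$time_h[i])) "      "
                  else sprintf("t=%g h", cmp$time_h[i]),
                  cmp$p_corrected[i],
                  if (cmp$p_corrected[i] < x$alpha) " *" else ""))
    }
  }
  invisible(x)
}

#' Extract fitted trend coefficients
#'
#' @param object a `phepart` fit.
#' @param ... unused.
#' @return Data frame with one row per genotype/replicate: the pool and
#'   labelling slopes (with standard errors), the mean tyrosine labelling
#'   and the consumption rate feeding that replicate's fluxes.
#' @export
coef.phepart <- function(object, ...) {
  rows <- list()
  for (g in object$genotypes) {
    for (r in names(object$trajectories[[g]])) {
      tr <- object$trajectories[[g]][[r]]
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, replicate = r,
        dCdt = tr$pool_trend$slope,
        dCdt_se = sqrt(tr$pool_trend$slope_variance),
        dfdt = tr$frac_trend$slope,
        dfdt_se = sqrt(tr$frac_trend$slope_variance),
        f_tyr = tr$f_tyr, vc = tr$vc,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict fluxes at arbitrary times
#'
#' Evaluates the fitted flux model (closed form in the fitted trends) at
#' new times and averages across replicates within genotype.
#'
#' @param object a `phepart` fit.
#' @param times evaluation times in hours (default: the fitted grid).
#' @param genotype genotypes to include (default all).
#' @param ... unused.
#' @return Data frame `genotype, time_h, v1, v1_se, v2, v2_se`.
#' @export
predict.phepart <- function(object, times = NULL, genotype = NULL, ...) {
  times <- times %||% object$grid
  genotype <- genotype %||% object$genotypes
  out <- list()
  for (g in genotype) {
    trs <- object$trajectories[[g]]
    n <- length(trs)
    re <- lapply(trs, function(tr) {
      compute_fluxes(tr$pool_trend, tr$frac_trend,
                     list(mean = tr$f_tyr, variance = tr$f_tyr_variance),
                     list(value = tr$vc, variance = tr$vc_variance),
                     grid = times, enrichment = tr$enrichment,
                     include_ftyr_variance =
                       object$config$include_ftyr_variance,
                     include_intercept_variance =
                       object$config$include_intercept_variance)
    })
    v1 <- rowMeans(vapply(re, `[[`, numeric(length(times)), "v1"))
    v2 <- rowMeans(vapply(re, `[[`, numeric(length(times)), "v2"))
    v1_se <- sqrt(rowSums(vapply(re, `[[`, numeric(length(times)),
                                 "v1_variance"))) / n
    v2_se <- sqrt(rowSums(vapply(re, `[[`, numeric(length(times)),
                                 "v2_variance"))) / n
    out[[g]] <- data.frame(genotype = g, time_h = times, v1 = v1,
                           v1_se = v1_se, v2 = v2, v2_se = v2_se,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Residuals of the fitted linear trends
#'
#' @param object a `phepart` fit.
#' @param ... unused.
#' @return Data frame `genotype, replicate, variable, time_h, residual`
#'   for the pool and labelling trend fits.
#' @export
residuals.phepart <- function(object, ...) {
  if (object$config$pooling == "pooled") {
    rows <- lapply(object$genotypes, function(g) {
      ft <- object$fits[[g]]
      rbind(
        data.frame(genotype = g, replicate = "pooled",
                   variable = "pool_phe", time_h = ft$pool_trend$times,
                   residual = ft$pool_trend$residuals),
        data.frame(genotype = g, replicate = "pooled",
                   variable = "frac_phe", time_h = ft$frac_trend$times,
                   residual = ft$frac_trend$residuals))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  rows <- list()
  for (g in object$genotypes) {
    for (r in names(object$fits[[g]])) {
      ft <- object$fits[[g]][[r]]
      rows[[length(rows) + 1L]] <- rbind(
        data.frame(genotype = g, replicate = r, variable = "pool_phe",
                   time_h = ft$pool_trend$times,
                   residual = ft$pool_trend$residuals),
        data.frame(genotype = g, replicate = r, variable = "frac_phe",
                   time_h = ft$frac_trend$times,
                   residual = ft$frac_trend$residuals))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot fitted flux trajectories
#'
#' Genotype-mean trajectories of the plastidial (v1) and cytosolic (v2)
#' fluxes with +/- 2 SE bands.
#'
#' @param x a `phepart` fit.
#' @param components which fluxes to draw.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return Invisibly `x`.
#' @export
plot.phepart <- function(x, components = c("v1", "v2"), ...) {
  components <- match.arg(components, c("v1", "v2"), several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(components)))
  on.exit(graphics::par(old))
  cols <- seq_along(x$genotypes)
  for (comp in components) {
    se_name <- paste0(comp, "_se")
    ys <- vapply(x$genotype_means, `[[`, numeric(length(x$grid)), comp)
    ses <- vapply(x$genotype_means, `[[`, numeric(length(x$grid)), se_name)
    graphics::matplot(x$grid, ys, type = "l", lty = 1, col = cols,
                      xlab = "time since feeding (h)",
                      ylab = sprintf("%s (nmol/gFW/h)", comp),
                      main = if (comp == "v1") "plastidial arogenate flux"
                      else "cytosolic phenylpyruvate flux", ...)
    for (i in seq_along(x$genotypes)) {
      graphics::polygon(c(x$grid, rev(x$grid)),
                        c(ys[, i] + 2 * ses[, i],
                          rev(ys[, i] - 2 * ses[, i])),
                        col = grDevices::adjustcolor(cols[i], alpha.f = 0.15),
                        border = NA)
    }
    graphics::legend("topleft", legend = x$genotypes, col = cols, lty = 1,
                     bty = "n")
  }
  invisible(x)
}

#' Simulate new labelling datasets from a fitted model
#'
#' Parametric simulation: for each genotype an exact-linear scenario is
#' built from the genotype-mean fitted parameters, with noise magnitudes
#' estimated from the trend residuals (pool CV from the pool residual
#' s.d. relative to the mean fitted pool; fraction s.d. from the
#' labelling residuals).
#'
#' @param object a `phepart` fit.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` [labeling_data()] objects.
#' @export
simulate.phepart <- function(object, nsim = 1, seed = NULL, ...) {
  cf <- coef(object)
  times <- sort(unique(object$data$time_h[object$data$variable ==
                                            "pool_phe"]))
  pf_with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      parts <- lapply(object$genotypes, function(g) {
        cg <- cf[cf$genotype == g, , drop = FALSE]
        trs <- object$trajectories[[g]]
        pool_res <- unlist(lapply(trs, function(tr) tr$pool_trend$residuals))
        frac_res <- unlist(lapply(trs, function(tr) tr$frac_trend$residuals))
        C0 <- mean(vapply(trs, function(tr) tr$pool_trend$intercept,
                          numeric(1)))
        f0 <- mean(vapply(trs, function(tr) tr$frac_trend$intercept,
                          numeric(1)))
        Cbar <- C0 + mean(cg$dCdt) * mean(times)
        scn <- flux_scenario(
          mode = "exact_linear", C0 = C0, dCdt = mean(cg$dCdt),
          f0 = min(max(f0, 0), 1), dfdt = mean(cg$dfdt),
          f_tyr = mean(cg$f_tyr), vc = mean(cg$vc),
          noise_cv_pool = stats::sd(pool_res) / Cbar,
          noise_cv_emission = stats::sd(pool_res) / Cbar,
          noise_sd_frac = stats::sd(frac_res),
          replicates = length(trs), times = times, seed = NULL)
        as.data.frame(simulate_exact_linear(scn, genotype = g)$data)
      })
      labeling_data(do.call(rbind, parts))
    })
  })
}
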