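# Genotype comparison: vc rescaling for export-impaired lines and the
# statistical contrasts of fluxes and flux trends between genotypes.

#' Rescale the control consumption rate for a perturbed genotype
#'
#' Perturbed (e.g. RNAi) lines emit a fraction of the control's
#' phenylalanine-derived volatiles; their consumption rate is taken as the
#' control \eqn{v_c} times the mean of those emission fractions.
#'
#' @param vc_control control consumption rate, `>= 0`.
#' @param emission_fractions per-line total-emission fractions of control
#'   (positive; e.g. `c(0.7, 0.6)` for two lines emitting 70% and 60% of
#'   control).
#' @return The scaled \eqn{v_c}.
#' @export
#' @examples
#' scale_consumption_rate(10, c(0.7, 0.6))  # 6.5
scale_consumption_rate <- function(vc_control, emission_fractions) {
  pf_check_numeric(vc_control, "vc_control")
  if (vc_control < 0) {
    pf_stop("phepart_negative_value", "vc_control must be >= 0")
  }
  if (length(emission_fractions) == 0) {
    pf_stop("phepart_empty_fractions",
            "emission_fractions must contain at least one value")
  }
  pf_check_numeric(emission_fractions, "emission_fractions")
  if (any(emission_fractions <= 0)) {
    pf_stop("phepart_bad_config", "emission fractions must be > 0")
  }
  vc_control * mean(emission_fractions)
}

# Welch two-sample t-test with a guard for degenerate (zero-variance)
# groups, where t.test() would fail on "essentially constant" data.
pf_two_sample <- function(a, b) {
  tol <- 1e-10 * max(1, abs(mean(a)), abs(mean(b)))
  if (stats::sd(a) < tol && stats::sd(b) < tol) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      list(stat = 0, p = 1)
    } else {
      list(stat = sign(mean(a) - mean(b)) * Inf, p = 0)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    list(stat = unname(tt$statistic), p = tt$p.value)
  }
}

pf_comparison_row <- function(labels, quantity, time_h, estimate_a,
                              estimate_b, n_a, n_b, stat, p_raw, m, mode) {
  out <- data.frame(
    comparison = paste(labels, collapse = " vs "),
    quantity = quantity, time_h = time_h,
    estimate_a = estimate_a, estimate_b = estimate_b,
    n_a = n_a, n_b = n_b, stat = stat, p_raw = p_raw,
    p_corrected = min(1, m * p_raw), mode = mode,
    stringsAsFactors = FALSE)
  class(out) <- c("genotype_comparison", "data.frame")
  out
}

#' Compare absolute fluxes between two genotypes at a time point
#'
#' Per-replicate mode (default): a Welch (unequal-variance) two-sample
#' two-tailed t-test on the per-replicate flux estimates. Pooled mode: a
#' z-style statistic from the two point estimates and their delta-method
#' variances. The raw p-value is Bonferroni-corrected with factor `m`
#' (capped at 1).
#'
#' @param group_a,group_b per-replicate flux values (replicate mode, each
#'   of length `>= 2`) or scalar point estimates (pooled mode).
#' @param m number of comparisons corrected over (default 1).
#' @param mode `"replicate"` or `"pooled"`.
#' @param var_a,var_b delta-method variances of the estimates (pooled mode
#'   only).
#' @param labels length-2 labels for the groups.
#' @param quantity,time_h bookkeeping fields for the output row.
#' @return A one-row `genotype_comparison` data frame with columns
#'   `comparison`, `quantity`, `time_h`, `estimate_a`, `estimate_b`,
#'   `n_a`, `n_b`, `stat`, `p_raw`, `p_corrected`, `mode`.
#' @export
compare_absolute_fluxes <- function(group_a, group_b, m = 1,
                                    mode = c("replicate", "pooled"),
                                    var_a = NULL, var_b = NULL,
                                    labels = c("group_a", "group_b"),
                                    quantity = "v1", time_h = NA_real_) {
  mode <- match.arg(mode)
  pf_check_numeric(group_a, "group_a")
  pf_check_numeric(group_b, "group_b")
  if (mode == "replicate") {
    if (length(group_a) < 2 || length(group_b) < 2) {
      pf_stop("phepart_insufficient_replicates",
              "need >= 2 replicate values per group for a t-test")
    }
    res <- pf_two_sample(group_a, group_b)
    pf_comparison_row(labels, quantity, time_h, mean(group_a),
                      mean(group_b), length(group_a), length(group_b),
                      res$stat, res$p, m, "replicate")
  } else {
    if (is.null(var_a) || is.null(var_b)) {
      pf_stop("phepart_bad_config",
              "pooled mode requires var_a and var_b")
    }
    se2 <- var_a + var_b
    if (se2 == 0) {
      z <- if (isTRUE(all.equal(group_a, group_b))) 0 else
        sign(group_a - group_b) * Inf
      p <- if (z == 0) 1 else 0
    } else {
      z <- (group_a - group_b) / sqrt(se2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    pf_comparison_row(labels, quantity, time_h, group_a, group_b,
                      1L, 1L, z, p, m, "pooled")
  }
}

# OLS slope of a component of one trajectory over its grid.
pf_traj_slope <- function(traj, component) {
  t <- traj$grid
  y <- traj[[component]]
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' Compare the rate of change of a flux between genotypes
#'
#' Tests whether the cytosolic-pathway flux `v2` (or `v1`) changes at a
#' different rate in one genotype than the other. The default `"slopes"`
#' mode fits an ordinary least-squares slope of the flux over the grid for
#' every replicate trajectory and compares the two groups of slopes with a
#' Welch two-sample t-test (genotypes are independent groups). The
#' `"paired_times"` mode instead pairs the group-mean flux values at
#' matched grid times and applies a paired two-tailed t-test; it mirrors a
#' paired-sample reading of the contrast but treats grid points as
#' independent, which overstates the information content -- it is provided
#' as an explicit alternative, and the mode used is recorded in the
#' result.
#'
#' @param trajs_a,trajs_b a `flux_trajectory` or list of per-replicate
#'   `flux_trajectory` objects, one per genotype, on identical grids.
#' @param mode `"slopes"` (default) or `"paired_times"`.
#' @param component `"v2"` (default) or `"v1"`.
#' @param m Bonferroni factor.
#' @param labels length-2 genotype labels.
#' @return A one-row `genotype_comparison` data frame; `mode` records the
#'   procedure used.
#' @export
compare_flux_trends <- function(trajs_a, trajs_b,
                                mode = c("slopes", "paired_times"),
                                component = c("v2", "v1"), m = 1,
                                labels = c("group_a", "group_b")) {
  mode <- match.arg(mode)
  component <- match.arg(component)
  as_list <- function(x) if (inherits(x, "flux_trajectory")) list(x) else x
  trajs_a <- as_list(trajs_a)
  trajs_b <- as_list(trajs_b)
  stopifnot(all(vapply(c(trajs_a, trajs_b), inherits, logical(1),
                       "flux_trajectory")))
  grids <- lapply(c(trajs_a, trajs_b), `[[`, "grid")
  if (!all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])),
                  logical(1)))) {
    pf_stop("phepart_grid_mismatch",
            "all trajectories must share the same grid")
  }
  if (mode == "slopes") {
    sa <- vapply(trajs_a, pf_traj_slope, numeric(1), component = component)
    sb <- vapply(trajs_b, pf_traj_slope, numeric(1), component = component)
    if (length(sa) < 2 || length(sb) < 2) {
      pf_stop("phepart_insufficient_replicates",
              "slopes mode needs >= 2 replicate trajectories per group")
    }
    res <- pf_two_sample(sa, sb)
    pf_comparison_row(labels, paste0(component, "_slope"), NA_real_,
                      mean(sa), mean(sb), length(sa), length(sb),
                      res$stat, res$p, m, "slopes")
  } else {
    mean_traj <- function(trs) {
      rowMeans(vapply(trs, `[[`, numeric(length(trs[[1]]$grid)), component))
    }
    ya <- mean_traj(trajs_a)
    yb <- mean_traj(trajs_b)
    d <- ya - yb
    if (stats::sd(d) == 0) {
      stat <- if (isTRUE(all.equal(mean(d), 0))) 0 else sign(mean(d)) * Inf
      p <- if (stat == 0) 1 else 0
    } else {
      tt <- stats::t.test(ya, yb, paired = TRUE)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    pf_comparison_row(labels, paste0(component, "_paired"), NA_real_,
                      mean(ya), mean(yb), length(trajs_a), length(trajs_b),
                      stat, p, m, "paired_times")
  }
}

#' @export
print.genotype_comparison <- function(x, ...) {
  cat("<genotype_comparison>\n")
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}
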