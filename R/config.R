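# Analysis configuration.

#' Analysis configuration for flux partitioning
#'
#' Collects the tunable parameters of the analysis. The defaults reproduce
#' the study design the package models: a 0-6 h feeding window evaluated
#' every 6 minutes (0.1 h), per-replicate trend fitting, Welch t-tests with
#' Bonferroni correction at alpha = 0.05.
#'
#' @param grid_start,grid_end,grid_step flux evaluation grid, hours.
#'   Default 0 to 6 h in steps of 0.1 h (6 min, 61 points).
#' @param alpha significance level for genotype comparisons.
#' @param bonferroni_m number of comparisons corrected over; `NULL` (the
#'   default) uses the number of per-genotype absolute-flux comparisons
#'   actually performed (one per compared time point).
#' @param pooling `"replicate"` fits trends per biological replicate and
#'   summarises fluxes across replicates (default); `"pooled"` fits one
#'   trend per genotype from all replicates jointly.
#' @param control name of the reference genotype; `NULL` uses a genotype
#'   literally named `"control"` if present, otherwise the first genotype.
#' @param rnai_emission_fractions fractional total emission of perturbed
#'   genotypes relative to control, used to rescale the control consumption
#'   rate \eqn{v_c}: either a numeric vector applied to every non-control
#'   genotype, or a named list mapping genotype to a numeric vector. The
#'   scaled \eqn{v_c} is control \eqn{v_c \times} mean(fractions). `NULL`
#'   fits each genotype's own emission series instead.
#' @param include_ftyr_variance logical; include the variance of the mean
#'   tyrosine labelling fraction in the error propagation (default `TRUE`).
#' @param include_intercept_variance logical; also propagate the measured
#'   t = 0 intercepts' measurement variance (estimated from the trend
#'   residuals) with the induced slope shift. Default `FALSE`, matching
#'   the convention of holding intercepts constant; `TRUE` completes the
#'   error model so that propagated flux variances track the full
#'   replicate-to-replicate sampling variability.
#' @param enrichment_rate which labelled-pool balance to use:
#'   `"product"` (default) tracks d(f C)/dt with the full product rule;
#'   `"pool"` tracks C df/dt only (no dilution-by-growth term).
#' @param strict_emission if `TRUE`, a decreasing cumulative emission
#'   series is an error rather than a warning.
#' @param seed integer seed for any stochastic routine downstream.
#' @return A `flux_config` object (a validated list).
#' @seealso [read_flux_config()]
#' @export
flux_config <- function(grid_start = 0, grid_end = 6, grid_step = 0.1,
                        alpha = 0.05, bonferroni_m = NULL,
                        pooling = c("replicate", "pooled"),
                        control = NULL,
                        rnai_emission_fractions = NULL,
                        include_ftyr_variance = TRUE,
                        include_intercept_variance = FALSE,
                        enrichment_rate = c("product", "pool"),
                        strict_emission = FALSE,
                        seed = NULL) {
  pooling <- match.arg(pooling)
  enrichment_rate <- match.arg(enrichment_rate)
  pf_check_numeric(grid_start, "grid_start")
  pf_check_numeric(grid_end, "grid_end")
  pf_check_numeric(grid_step, "grid_step")
  if (grid_step <= 0) pf_stop("phepart_bad_config", "grid_step must be > 0")
  if (grid_end <= grid_start) {
    pf_stop("phepart_bad_config", "grid_end must exceed grid_start")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    pf_stop("phepart_bad_config", "alpha must lie in (0, 1)")
  }
  if (!is.null(bonferroni_m) &&
      (!is.numeric(bonferroni_m) || bonferroni_m < 1)) {
    pf_stop("phepart_bad_config", "bonferroni_m must be >= 1")
  }
  if (!is.null(rnai_emission_fractions)) {
    fr <- rnai_emission_fractions
    if (is.numeric(fr)) fr <- list(fr)
    ok <- all(vapply(fr, function(v) {
      is.numeric(v) && length(v) >= 1 && all(is.finite(v)) && all(v > 0)
    }, logical(1)))
    if (!ok) {
      pf_stop("phepart_bad_config",
              "rnai_emission_fractions must be positive numeric vectors")
    }
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(grid_start = grid_start, grid_end = grid_end,
                 grid_step = grid_step, alpha = alpha,
                 bonferroni_m = bonferroni_m, pooling = pooling,
                 control = control,
                 rnai_emission_fractions = rnai_emission_fractions,
                 include_ftyr_variance = include_ftyr_variance,
                 include_intercept_variance = include_intercept_variance,
                 enrichment_rate = enrichment_rate,
                 strict_emission = strict_emission, seed = seed),
            class = "flux_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Fields mirror the arguments of [flux_config()]; arguments passed through
#' `...` override values from the file (so callers can override file values
#' the way command-line flags would).
#'
#' @param path path to a YAML file.
#' @param ... overrides, as named [flux_config()] arguments.
#' @return A `flux_config` object.
#' @export
read_flux_config <- function(path, ...) {
  if (!file.exists(path)) {
    pf_stop("phepart_io_error", sprintf("config file not found: %s", path))
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(flux_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    pf_stop("phepart_bad_config",
            sprintf("unknown config field(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(flux_config, vals)
}

#' @export
print.flux_config <- function(x, ...) {
  cat("<flux_config>\n")
  cat(sprintf("  grid: %g to %g h by %g h\n",
              x$grid_start, x$grid_end, x$grid_step))
  cat(sprintf("  alpha: %g, pooling: %s, enrichment balance: %s\n",
              x$alpha, x$pooling, x$enrichment_rate))
  if (!is.null(x$control)) cat(sprintf("  control genotype: %s\n", x$control))
  if (!is.null(x$rnai_emission_fractions)) {
    cat("  vc rescaling from emission fractions: yes\n")
  }
  invisible(x)
}
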