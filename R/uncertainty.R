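# First-order (delta-method) error propagation for flux variances, with a
# Monte-Carlo oracle.
#
# Flux values are functions y = f(x1, ..., xn) of the estimated slopes
# (dC/dt, df/dt), the consumption rate vc and optionally the mean tyrosine
# labelling fTyr; treating the inputs as independent,
#   Var(y) = sum_i (df/dxi)^2 Var(xi).
# Fixed intercepts are data and contribute zero variance.

#' First-order variance propagation
#'
#' `Var(y) = sum(partials^2 * variances)` for independent inputs.
#'
#' @param partials partial derivatives of the output with respect to each
#'   input, evaluated at the point estimates.
#' @param variances input variances (same length, all `>= 0`).
#' @return The propagated output variance.
#' @export
#' @examples
#' # y = x1 * x2 at x1 = 3 (Var 0.04), x2 = 5 (Var 0.09)
#' propagate_variance(c(5, 3), c(0.04, 0.09))  # 1.81
propagate_variance <- function(partials, variances) {
  pf_check_numeric(partials, "partials")
  pf_check_numeric(variances, "variances")
  if (length(partials) != length(variances)) {
    pf_stop("phepart_length_mismatch",
            "partials and variances must have equal length")
  }
  if (any(variances < 0)) {
    pf_stop("phepart_negative_variance", "variances must be >= 0")
  }
  sum(partials^2 * variances)
}

# Analytic partial derivatives of (v1, v2) at grid time t with respect to
# the random inputs (dC/dt slope, df/dt slope, vc, fTyr, and optionally
# the measured intercepts C0, f0). With C(t) = C0 + bC t and
# f(t) = f0 + bf t:
#   product:  N(t) = f bC + C bf + vc f ; pool: N(t) = C bf + vc f
#   v2 = N / fTyr,  v1 = bC - v2 + vc.
# An intercept error also shifts the fitted slope (coupling kC = dbC/dC0,
# kf = dbf/df0), so the intercept partials are total derivatives.
pf_flux_partials <- function(t, C, f, bC, bf, vc, fTyr, enrichment,
                             kC = 0, kf = 0) {
  if (enrichment == "product") {
    dN_dbC <- f + t * bf       # f directly, plus C's dependence on bC
    dN_dbf <- t * bC + C + vc * t
    dN_dC0 <- f * kC + (1 + t * kC) * bf
    dN_df0 <- (1 + t * kf) * (bC + vc) + C * kf
  } else {
    dN_dbC <- t * bf
    dN_dbf <- C + vc * t
    dN_dC0 <- (1 + t * kC) * bf
    dN_df0 <- (1 + t * kf) * vc + C * kf
  }
  dN_dvc <- f
  v2 <- (if (enrichment == "product") f * bC + C * bf else C * bf)
  v2 <- (v2 + vc * f) / fTyr
  n <- length(t)
  list(
    v2 = cbind(bC = dN_dbC / fTyr, bf = dN_dbf / fTyr,
               vc = dN_dvc / fTyr, fTyr = -v2 / fTyr,
               C0 = rep_len(dN_dC0 / fTyr, n),
               f0 = rep_len(dN_df0 / fTyr, n)),
    v1 = cbind(bC = 1 - dN_dbC / fTyr, bf = -dN_dbf / fTyr,
               vc = 1 - dN_dvc / fTyr, fTyr = v2 / fTyr,
               C0 = rep_len(kC - dN_dC0 / fTyr, n),
               f0 = rep_len(-dN_df0 / fTyr, n))
  )
}

#' Delta-method variances of the flux trajectories
#'
#' Propagates the variances of the random inputs -- the pool slope, the
#' labelling slope, the consumption rate and (optionally) the mean
#' tyrosine labelling -- through the flux equations at every grid point.
#' By default the fixed t = 0 intercepts are treated as constants (zero
#' variance); `include_intercept_variance = TRUE` instead completes the
#' error model by propagating the intercepts' measurement variance
#' (estimated by each trend's residual variance) together with the
#' induced shift of the fitted slope.
#'
#' @inheritParams compute_fluxes
#' @return List with per-grid-point `v1_variance` and `v2_variance`, and
#'   the scalar `vc_variance`.
#' @export
flux_variances <- function(pool_trend, frac_trend, f_tyr, vc,
                           grid = seq(0, 6, by = 0.1),
                           enrichment = c("product", "pool"),
                           include_ftyr_variance = TRUE,
                           include_intercept_variance = FALSE) {
  enrichment <- match.arg(enrichment)
  stopifnot(inherits(pool_trend, "linear_trend"),
            inherits(frac_trend, "linear_trend"))
  fT <- pf_ftyr_input(f_tyr)
  vcv <- pf_vc_input(vc)
  if (fT$mean <= 0) {
    pf_stop("phepart_ftyr_nonpositive",
            "mean tyrosine labelling must be > 0")
  }
  C <- evaluate_trend(pool_trend, grid)
  f <- evaluate_trend(frac_trend, grid)
  part <- pf_flux_partials(grid, C, f, pool_trend$slope, frac_trend$slope,
                           vcv$value, fT$mean, enrichment,
                           kC = pool_trend$intercept_slope_coupling %||% 0,
                           kf = frac_trend$intercept_slope_coupling %||% 0)
  variances <- c(bC = pool_trend$slope_variance,
                 bf = frac_trend$slope_variance,
                 vc = vcv$variance,
                 fTyr = if (include_ftyr_variance) fT$variance else 0,
                 C0 = if (include_intercept_variance)
                   pool_trend$intercept_variance %||% 0 else 0,
                 f0 = if (include_intercept_variance)
                   frac_trend$intercept_variance %||% 0 else 0)
  v1_var <- vapply(seq_along(grid), function(i) {
    propagate_variance(part$v1[i, ], variances)
  }, numeric(1))
  v2_var <- vapply(seq_along(grid), function(i) {
    propagate_variance(part$v2[i, ], variances)
  }, numeric(1))
  list(v1_variance = v1_var, v2_variance = v2_var,
       vc_variance = vcv$variance)
}

#' Monte-Carlo flux variances (validation oracle for the delta method)
#'
#' Draws the random inputs independently from normal distributions centred
#' at their point estimates, recomputes the flux trajectories for every
#' draw, and returns the empirical per-grid-point variances. Tyrosine
#' labelling draws falling outside (0, 1] are rejected and redrawn.
#' Deterministic given `seed`.
#'
#' @inheritParams compute_fluxes
#' @param n_draws number of Monte-Carlo draws (`>= 100`).
#' @param seed integer seed (the caller's RNG state is restored).
#' @return List with empirical `v1_variance`, `v2_variance` (per grid
#'   point) and `n_draws`.
#' @export
monte_carlo_flux_variance <- function(pool_trend, frac_trend, f_tyr, vc,
                                      grid = seq(0, 6, by = 0.1),
                                      n_draws = 1e5, seed = NULL,
                                      enrichment = c("product", "pool"),
                                      include_ftyr_variance = TRUE) {
  enrichment <- match.arg(enrichment)
  if (!is.numeric(n_draws) || n_draws < 100) {
    pf_stop("phepart_bad_draws", "n_draws must be >= 100")
  }
  n_draws <- as.integer(n_draws)
  fT <- pf_ftyr_input(f_tyr)
  vcv <- pf_vc_input(vc)
  if (fT$mean <= 0) {
    pf_stop("phepart_ftyr_nonpositive",
            "mean tyrosine labelling must be > 0")
  }
  C0 <- pool_trend$intercept
  f0 <- frac_trend$intercept
  pf_with_seed(seed, {
    bC <- stats::rnorm(n_draws, pool_trend$slope,
                       sqrt(pool_trend$slope_variance))
    bf <- stats::rnorm(n_draws, frac_trend$slope,
                       sqrt(frac_trend$slope_variance))
    vc_d <- stats::rnorm(n_draws, vcv$value, sqrt(vcv$variance))
    if (include_ftyr_variance && fT$variance > 0) {
      fT_d <- stats::rnorm(n_draws, fT$mean, sqrt(fT$variance))
      bad <- which(fT_d <= 0 | fT_d > 1)
      while (length(bad) > 0) {
        fT_d[bad] <- stats::rnorm(length(bad), fT$mean, sqrt(fT$variance))
        bad <- bad[fT_d[bad] <= 0 | fT_d[bad] > 1]
      }
    } else {
      fT_d <- rep(fT$mean, n_draws)
    }
    G <- length(grid)
    Fm <- f0 + outer(bf, grid)           # n_draws x G labelling fractions
    Cm <- C0 + outer(bC, grid)
    N <- if (enrichment == "product") Fm * bC + Cm * bf else Cm * bf
    V2 <- (N + vc_d * Fm) / fT_d
    V1 <- (bC + vc_d) - V2
    col_var <- function(M) {
      mu <- colMeans(M)
      (colSums(M^2) - n_draws * mu^2) / (n_draws - 1)
    }
    list(v1_variance = col_var(V1), v2_variance = col_var(V2),
         n_draws = n_draws)
  })
}
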