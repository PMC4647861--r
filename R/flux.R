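# Mass-balance flux model.
#
# The phenylalanine pool obeys two balances over the feeding window:
#   total pool:     dC/dt       = v1 + v2 - vc
#   labelled pool:  d(f C)/dt   = v2 * fTyr - vc * f
# where v1 is the plastidial arogenate-pathway flux (unlabelled product,
# since tyrosine is not its amino donor), v2 the cytosolic phenylpyruvate-
# pathway flux (sole entry route of the 15N label), vc the constant
# consumption flux into volatiles, f the phenylalanine labelling fraction
# and fTyr the (plateaued) tyrosine labelling fraction. Inverting them:
#   v2(t) = [d(f C)/dt + vc f(t)] / fTyr
#   v1(t) = dC/dt - v2(t) + vc
# With affine C(t) and f(t) the labelled-pool rate has the closed form
# d(f C)/dt = f dC/dt + C df/dt (exact product rule, not a finite
# difference).

# Normalise f_tyr / vc arguments to (value, variance) pairs.
pf_ftyr_input <- function(f_tyr) {
  if (is.numeric(f_tyr)) f_tyr <- list(mean = f_tyr, variance = 0)
  stopifnot(is.list(f_tyr), !is.null(f_tyr$mean))
  f_tyr$variance <- f_tyr$variance %||% 0
  f_tyr
}

pf_vc_input <- function(vc) {
  if (inherits(vc, "linear_trend")) {
    vc <- list(value = vc$slope, variance = vc$slope_variance)
  } else if (is.numeric(vc)) {
    vc <- list(value = vc, variance = 0)
  }
  stopifnot(is.list(vc), !is.null(vc$value))
  vc$variance <- vc$variance %||% 0
  vc
}

#' Rate of change of the labelled phenylalanine pool
#'
#' The product rule applied to the two affine trends:
#' `d(f C)/dt = f dC/dt + C df/dt`.
#'
#' @param C pool size value(s), nmol/gFW.
#' @param dCdt pool slope, nmol/gFW/h.
#' @param f labelling fraction value(s) in `[0, 1]`.
#' @param dfdt labelling-fraction slope, 1/h.
#' @return Labelled-pool rate, nmol/gFW/h.
#' @export
#' @examples
#' product_rate(110, 5, 0.04, 0.02)  # 2.4
product_rate <- function(C, dCdt, f, dfdt) {
  pf_check_numeric(C, "C"); pf_check_numeric(dCdt, "dCdt")
  pf_check_numeric(f, "f"); pf_check_numeric(dfdt, "dfdt")
  if (any(f < 0 | f > 1)) {
    pf_stop("phepart_fraction_range", "f must lie in [0, 1]")
  }
  f * dCdt + C * dfdt
}

#' Pathway fluxes on a time grid from fitted trends
#'
#' Inverts the total-pool and labelled-pool mass balances to obtain the
#' plastidial arogenate-pathway flux `v1` and the cytosolic
#' phenylpyruvate-pathway flux `v2` at every grid point, together with
#' delta-method variances (see [flux_variances()]). By construction the
#' conservation identity `v1(t) + v2(t) - vc = dC/dt` holds exactly at
#' every grid point. Negative flux estimates are retained with a warning,
#' never clipped: clipping would silently break the conservation identity.
#'
#' @param pool_trend `linear_trend` for the phenylalanine pool size.
#' @param frac_trend `linear_trend` for the phenylalanine labelling
#'   fraction.
#' @param f_tyr mean tyrosine labelling: a number, or a list with `mean`
#'   and `variance` as returned by [mean_tyrosine_labelling()]. Must be
#'   positive: the labelled-pool balance is divided by it.
#' @param vc consumption rate: a number, a list with `value`/`variance`,
#'   or the `linear_trend` from [estimate_consumption_rate()].
#' @param grid evaluation times, hours (default every 6 min over 0-6 h).
#' @param enrichment `"product"` (full product rule, default) or `"pool"`
#'   (labelled-pool balance tracks `C df/dt` only).
#' @param include_ftyr_variance include Var(fTyr) in the propagation.
#' @param include_intercept_variance also propagate the t = 0 intercepts'
#'   measurement variance (default `FALSE`: intercepts are constants).
#' @return A `flux_trajectory`: `grid`, `v1`, `v2`, `vc` (scalar),
#'   `v1_variance`, `v2_variance`, `vc_variance`, plus the inputs.
#' @export
#' @examples
#' pool <- linear_trend(slope = 5, intercept = 100)
#' frac <- linear_trend(slope = 0.02, intercept = 0)
#' tr <- compute_fluxes(pool, frac, f_tyr = 0.8, vc = 10, grid = c(0, 6))
#' tr$v2  # 2.5 at t0, 5.5 at t6
compute_fluxes <- function(pool_trend, frac_trend, f_tyr, vc,
                           grid = seq(0, 6, by = 0.1),
                           enrichment = c("product", "pool"),
                           include_ftyr_variance = TRUE,
                           include_intercept_variance = FALSE) {
  enrichment <- match.arg(enrichment)
  stopifnot(inherits(pool_trend, "linear_trend"),
            inherits(frac_trend, "linear_trend"))
  pf_check_numeric(grid, "grid")
  if (length(grid) == 0) {
    pf_stop("phepart_empty_grid", "grid must contain at least one time")
  }
  fT <- pf_ftyr_input(f_tyr)
  vcv <- pf_vc_input(vc)
  if (fT$mean <= 0) {
    pf_stop("phepart_ftyr_nonpositive",
            paste0("mean tyrosine labelling must be > 0: the ",
                   "phenylpyruvate-pathway flux divides the labelled-pool ",
                   "balance by it"))
  }
  C <- evaluate_trend(pool_trend, grid)
  f <- evaluate_trend(frac_trend, grid)
  if (any(f < -1e-9 | f > 1 + 1e-9)) {
    warning("fitted labelling fraction leaves [0, 1] on the grid",
            call. = FALSE)
  }
  bC <- pool_trend$slope
  bf <- frac_trend$slope
  dfc <- if (enrichment == "product") f * bC + C * bf else C * bf
  v2 <- (dfc + vcv$value * f) / fT$mean
  v1 <- bC - v2 + vcv$value
  if (any(v1 < 0) || any(v2 < 0)) {
    warning("negative flux estimate(s) on the grid; retained unclipped",
            call. = FALSE)
  }
  vars <- flux_variances(pool_trend, frac_trend, fT, vcv, grid,
                         enrichment = enrichment,
                         include_ftyr_variance = include_ftyr_variance,
                         include_intercept_variance =
                           include_intercept_variance)
  structure(list(grid = grid, v1 = v1, v2 = v2, vc = vcv$value,
                 v1_variance = vars$v1_variance,
                 v2_variance = vars$v2_variance,
                 vc_variance = vcv$variance,
                 f_tyr = fT$mean, f_tyr_variance = fT$variance,
                 enrichment = enrichment,
                 pool_trend = pool_trend, frac_trend = frac_trend),
            class = "flux_trajectory")
}

#' Flux ratio v2 / v1 at a grid time
#'
#' The relative contribution of the cytosolic phenylpyruvate pathway.
#'
#' @param traj a `flux_trajectory`.
#' @param t a time on the trajectory's grid.
#' @return `v2(t) / v1(t)`.
#' @export
flux_ratio <- function(traj, t) {
  stopifnot(inherits(traj, "flux_trajectory"))
  idx <- which(abs(traj$grid - t) < 1e-8)
  if (length(idx) == 0) {
    pf_stop("phepart_grid_mismatch",
            sprintf("t = %g is not on the trajectory grid", t))
  }
  idx <- idx[1]
  if (traj$v1[idx] == 0) {
    pf_stop("phepart_undefined_ratio",
            sprintf("v1(t = %g) is zero: ratio undefined", t))
  }
  traj$v2[idx] / traj$v1[idx]
}

#' Percent change of a flux relative to a reference
#'
#' On the printed scale: `100 (reference - test) / reference`, so a
#' positive value means the test flux is lower than the reference (32
#' means 32% lower).
#'
#' @param reference reference (e.g. control) flux value, non-zero.
#' @param test compared flux value.
#' @return Percent difference.
#' @export
percent_change <- function(reference, test) {
  pf_check_numeric(reference, "reference")
  pf_check_numeric(test, "test")
  if (any(reference == 0)) {
    pf_stop("phepart_zero_reference", "reference flux must be non-zero")
  }
  100 * (reference - test) / reference
}

#' @export
print.flux_trajectory <- function(x, ...) {
  g <- range(x$grid)
  cat(sprintf("<flux_trajectory> %d grid points over [%g, %g] h\n",
              length(x$grid), g[1], g[2]))
  cat(sprintf("  v1: %.4g -> %.4g   v2: %.4g -> %.4g   vc: %.4g\n",
              x$v1[1], x$v1[length(x$v1)], x$v2[1], x$v2[length(x$v2)],
              x$vc))
  invisible(x)
}

#' Export a flux trajectory as a data frame
#'
#' @param x a `flux_trajectory`.
#' @param ... unused.
#' @return Data frame with one row per grid point:
#'   `time_h  v1  v1_var  v2  v2_var  vc  vc_var`.
#' @export
as.data.frame.flux_trajectory <- function(x, ...) {
  data.frame(time_h = x$grid, v1 = x$v1, v1_var = x$v1_variance,
             v2 = x$v2, v2_var = x$v2_variance,
             vc = x$vc, vc_var = x$vc_variance)
}
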