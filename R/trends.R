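# Fixed-intercept linear trend estimation.
#
# Over the 0-6 h feeding window the phenylalanine pool size and its
# fractional labelling increase linearly, and cumulative volatile emission
# is linear in time, so each series is summarised by a single slope. The
# intercept is pinned to the measured t = 0 value (it is data, not a
# parameter), which leaves one estimated parameter and n - 1 residual
# degrees of freedom.

#' Construct a linear trend object directly
#'
#' Mostly used by the synthetic-data generator and in tests to build
#' noise-free trends with known slopes.
#'
#' @param slope slope, series units per hour.
#' @param intercept fixed intercept, series units.
#' @param slope_variance,residual_variance variances (default 0).
#' @param intercept_variance measurement variance of the t = 0 value
#'   (default 0: the intercept is treated as a constant).
#' @param intercept_slope_coupling sensitivity of the fitted slope to an
#'   error in the intercept, `d slope / d y0`; for the fixed-intercept
#'   least-squares fit this is `-sum(t) / sum(t^2)` (default 0 for a
#'   directly constructed trend).
#' @param n_points number of points behind the estimate.
#' @return A `linear_trend` object.
#' @export
linear_trend <- function(slope, intercept, slope_variance = 0,
                         residual_variance = 0, intercept_variance = 0,
                         intercept_slope_coupling = 0,
                         n_points = NA_integer_) {
  pf_check_numeric(slope, "slope")
  pf_check_numeric(intercept, "intercept")
  if (slope_variance < 0 || residual_variance < 0 ||
      intercept_variance < 0) {
    pf_stop("phepart_negative_variance", "variances must be >= 0")
  }
  structure(list(slope = slope, slope_variance = slope_variance,
                 intercept = intercept,
                 residual_variance = residual_variance,
                 intercept_variance = intercept_variance,
                 intercept_slope_coupling = intercept_slope_coupling,
                 n_points = n_points, times = NULL, residuals = NULL),
            class = "linear_trend")
}

#' Least-squares slope through a fixed, measured intercept
#'
#' Fits `y = y0 + b t` with `y0` held at the measured t = 0 value. The
#' slope is `b = sum(t (y - y0)) / sum(t^2)`; the residual variance uses
#' `n - 1` degrees of freedom (only the slope is estimated), and the slope
#' variance is the residual variance divided by `sum(t^2)`.
#'
#' @param times sampling times, hours; at least two points, not all zero.
#' @param values observed series values.
#' @param intercept the measured t = 0 value, held fixed.
#' @return A `linear_trend` with `slope`, `slope_variance`, `intercept`,
#'   `residual_variance`, `n_points`, plus the per-point `residuals`.
#' @export
#' @examples
#' fit_fixed_intercept_slope(c(2, 4, 6), c(110, 120, 130), 100)  # slope 5
fit_fixed_intercept_slope <- function(times, values, intercept) {
  pf_check_numeric(times, "times")
  pf_check_numeric(values, "values")
  pf_check_numeric(intercept, "intercept")
  n <- length(times)
  if (n < 2 || length(values) != n) {
    pf_stop("phepart_degenerate_fit",
            "need >= 2 (time, value) pairs of equal length")
  }
  st2 <- sum(times^2)
  if (st2 == 0) {
    pf_stop("phepart_degenerate_fit",
            "all times are zero: slope is not identifiable")
  }
  dy <- values - intercept
  slope <- sum(times * dy) / st2
  resid <- dy - slope * times
  residual_variance <- sum(resid^2) / (n - 1)
  # The residual variance doubles as an estimate of the single-point
  # measurement variance, applicable to the t = 0 measurement itself; an
  # intercept error e shifts the fitted slope by -e sum(t)/sum(t^2).
  out <- linear_trend(slope, intercept,
                      slope_variance = residual_variance / st2,
                      residual_variance = residual_variance,
                      intercept_variance = residual_variance,
                      intercept_slope_coupling = -sum(times) / st2,
                      n_points = n)
  out$times <- times
  out$residuals <- resid
  out
}

#' Evaluate a linear trend on a time grid
#'
#' @param trend a `linear_trend`.
#' @param grid times (hours) at which to evaluate.
#' @return `intercept + slope * grid`.
#' @export
evaluate_trend <- function(trend, grid) {
  stopifnot(inherits(trend, "linear_trend"))
  pf_check_numeric(grid, "grid")
  if (length(grid) == 0) {
    pf_stop("phepart_empty_grid", "grid must contain at least one time")
  }
  trend$intercept + trend$slope * grid
}

#' Mean tyrosine labelling fraction over the experiment
#'
#' Tyrosine labelling plateaus above 80% shortly after feeding, so it is
#' summarised by its arithmetic mean over the post-feeding time points,
#' with the variance of that mean (sample variance / n; 0 for a single
#' observation).
#'
#' @param values tyrosine labelling fractions in `[0, 1]`.
#' @return List with `mean`, `variance` (of the mean) and `n`.
#' @export
mean_tyrosine_labelling <- function(values) {
  pf_check_numeric(values, "values")
  if (length(values) < 1) {
    pf_stop("phepart_empty_series",
            "need at least one tyrosine labelling observation")
  }
  if (any(values < 0 | values > 1)) {
    pf_stop("phepart_fraction_range",
            "tyrosine labelling fractions must lie in [0, 1]")
  }
  n <- length(values)
  list(mean = mean(values),
       variance = if (n > 1) stats::var(values) / n else 0,
       n = n)
}

#' Phenylalanine consumption rate from cumulative volatile emission
#'
#' Cumulative emission of phenylalanine-derived volatiles increases
#' linearly, so the consumption flux \eqn{v_c} is taken constant over the
#' window and estimated as the fixed-intercept slope of the cumulative
#' series through 0 at the start of collection.
#'
#' @param times collection times, hours.
#' @param cumulative_emission cumulative emission, nmol/gFW; expected
#'   non-decreasing. Small decreases (measurement noise) produce a warning
#'   by default, an error with `strict = TRUE`.
#' @param strict logical, see above.
#' @return A `linear_trend` whose slope is \eqn{v_c} (nmol/gFW/h).
#' @export
#' @examples
#' estimate_consumption_rate(c(2, 4, 6), c(20, 40, 60))$slope  # 10
estimate_consumption_rate <- function(times, cumulative_emission,
                                      strict = FALSE) {
  pf_check_numeric(times, "times")
  pf_check_numeric(cumulative_emission, "cumulative_emission")
  ord <- order(times)
  em <- cumulative_emission[ord]
  if (any(diff(em) < 0)) {
    msg <- "cumulative emission decreases over time"
    if (strict) pf_stop("phepart_nonmonotone_emission", msg)
    warning(msg, call. = FALSE)
  }
  fit_fixed_intercept_slope(times, cumulative_emission, 0)
}

#' @export
print.linear_trend <- function(x, ...) {
  cat(sprintf(
    "<linear_trend> slope %.6g (var %.3g), fixed intercept %.6g, n = %s\n",
    x$slope, x$slope_variance, x$intercept,
    if (is.na(x$n_points)) "?" else x$n_points))
  invisible(x)
}
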