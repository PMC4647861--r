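# Observed-data model: long-format labelling time series.
#
# A labelling dataset is a tidy table with one row per measurement:
#   genotype   replicate   time_h   variable   value
# where `variable` is one of pool_phe (phenylalanine pool, nmol/gFW),
# frac_phe (15N fractional abundance of phenylalanine, in [0,1]),
# frac_tyr (15N fractional abundance of tyrosine, in [0,1]) and
# emission_total (cumulative phenylalanine-derived volatile emission,
# nmol/gFW). Rows with time_h = 0 are the measured intercepts used as fixed
# regression intercepts, stored as data rather than extrapolated.

pf_columns <- c("genotype", "replicate", "time_h", "variable", "value")
pf_variables <- c("pool_phe", "frac_phe", "frac_tyr", "emission_total")
pf_fraction_vars <- c("frac_phe", "frac_tyr")

#' Construct a labelling dataset from long-format observations
#'
#' Validates a data frame of labelling observations and returns it as a
#' `labeling_data` object in canonical order (genotype, replicate, variable,
#' time). Fractions must be proportions in `[0, 1]`; values above 1 for a
#' `frac_*` variable are treated as an error (suspected percent input),
#' never silently rescaled. Duplicate (genotype, replicate, variable, time)
#' rows are an error, not averaged.
#'
#' @param observations data frame with columns `genotype`, `replicate`,
#'   `time_h`, `variable`, `value`.
#' @return A `labeling_data` object (a sorted data frame).
#' @seealso [read_labeling_data()], [write_labeling_data()],
#'   [extract_series()]
#' @export
#' @examples
#' df <- data.frame(genotype = "control", replicate = "r1",
#'                  time_h = c(0, 2, 4, 6), variable = "pool_phe",
#'                  value = c(100, 110, 120, 130))
#' labeling_data(df)
labeling_data <- function(observations) {
  df <- as.data.frame(observations, stringsAsFactors = FALSE)
  validate_labeling_data(df)
  df <- df[order(df$genotype, df$replicate, df$variable, df$time_h),
           pf_columns, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("labeling_data", "data.frame")
  df
}

#' Validate a labelling dataset
#'
#' Checks the schema and the type invariants: fractions in `[0, 1]`, pools
#' and emission non-negative, times finite and non-negative, no duplicate
#' observations, and at least two distinct time points per
#' (genotype, replicate, variable) series. Each violation raises a distinct
#' classed error (e.g. `phepart_fraction_range`,
#' `phepart_duplicate_observation`).
#'
#' @param df data frame to validate.
#' @return Invisibly `TRUE` if valid.
#' @export
validate_labeling_data <- function(df) {
  missing <- setdiff(pf_columns, names(df))
  if (length(missing) > 0) {
    pf_stop("phepart_missing_column",
            sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) return(invisible(TRUE))
  if (!is.numeric(df$time_h)) {
    pf_stop("phepart_nonnumeric_value", "'time_h' must be numeric")
  }
  if (!is.numeric(df$value)) {
    pf_stop("phepart_nonnumeric_value", "'value' must be numeric")
  }
  if (any(!is.finite(df$time_h)) || any(df$time_h < 0)) {
    pf_stop("phepart_bad_time", "'time_h' must be finite and >= 0")
  }
  if (any(!is.finite(df$value))) {
    pf_stop("phepart_nonnumeric_value", "'value' contains non-finite entries")
  }
  unknown <- setdiff(unique(df$variable), pf_variables)
  if (length(unknown) > 0) {
    pf_stop("phepart_unknown_variable",
            sprintf("unknown variable(s): %s (expected %s)",
                    paste(unknown, collapse = ", "),
                    paste(pf_variables, collapse = ", ")))
  }
  frac <- df$variable %in% pf_fraction_vars
  if (any(df$value[frac] < 0 | df$value[frac] > 1)) {
    pf_stop("phepart_fraction_range",
            paste0("fractional labelling values must lie in [0, 1]; ",
                   "values > 1 suggest percent input, which must be ",
                   "converted to proportions upstream"))
  }
  if (any(df$value[!frac] < 0)) {
    pf_stop("phepart_negative_value",
            "pool and emission values must be >= 0")
  }
  key <- paste(df$genotype, df$replicate, df$variable, df$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1, ]
    pf_stop("phepart_duplicate_observation",
            sprintf("duplicate observation for (%s, %s, %s, t=%g)",
                    dup$genotype, dup$replicate, dup$variable, dup$time_h))
  }
  series <- paste(df$genotype, df$replicate, df$variable, sep = "\r")
  n_times <- tapply(df$time_h, series, function(t) length(unique(t)))
  if (any(n_times < 2)) {
    bad <- names(n_times)[which(n_times < 2)[1]]
    pf_stop("phepart_short_series",
            sprintf("series (%s) has fewer than 2 distinct time points",
                    gsub("\r", ", ", bad)))
  }
  invisible(TRUE)
}

#' Read a labelling dataset from a tab-separated file
#'
#' Expects a UTF-8 TSV with the exact header
#' `genotype  replicate  time_h  variable  value`. Intercepts are supplied
#' as rows with `time_h = 0`. All validation errors carry distinct classes
#' (missing column, non-numeric value, fraction out of range, duplicate
#' observation).
#'
#' @param path path to the TSV file.
#' @param config optional [flux_config()]; currently only carried through
#'   for provenance, the schema itself is fixed.
#' @return A validated [labeling_data()] object with each series sorted by
#'   time.
#' @export
read_labeling_data <- function(path, config = NULL) {
  if (!file.exists(path)) {
    pf_stop("phepart_io_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!identical(names(raw), pf_columns)) {
    missing <- setdiff(pf_columns, names(raw))
    pf_stop("phepart_missing_column",
            sprintf("header must be exactly '%s'%s",
                    paste(pf_columns, collapse = "\t"),
                    if (length(missing) > 0) {
                      sprintf(" (missing: %s)", paste(missing, collapse = ", "))
                    } else ""))
  }
  to_num <- function(x, name) {
    out <- suppressWarnings(as.numeric(x))
    if (any(is.na(out))) {
      pf_stop("phepart_nonnumeric_value",
              sprintf("non-numeric entry in column '%s': '%s'",
                      name, x[which(is.na(out))[1]]))
    }
    out
  }
  df <- data.frame(genotype = raw$genotype, replicate = raw$replicate,
                   time_h = if (nrow(raw)) to_num(raw$time_h, "time_h") else numeric(0),
                   variable = raw$variable,
                   value = if (nrow(raw)) to_num(raw$value, "value") else numeric(0),
                   stringsAsFactors = FALSE)
  labeling_data(df)
}

#' Write a labelling dataset to a tab-separated file
#'
#' Output is canonical: fixed column order, rows sorted by genotype,
#' replicate, variable and time, and fixed decimal formatting (4 decimals
#' for time, 6 for values), so identical datasets always produce
#' byte-identical files and `read_labeling_data(write_labeling_data(x))`
#' round-trips.
#'
#' @param x a [labeling_data()] object (or coercible data frame).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_labeling_data <- function(x, path) {
  if (!inherits(x, "labeling_data")) x <- labeling_data(x)
  lines <- paste(pf_columns, collapse = "\t")
  if (nrow(x) > 0) {
    lines <- c(lines, paste(x$genotype, x$replicate,
                            sprintf("%.4f", x$time_h), x$variable,
                            sprintf("%.6f", x$value), sep = "\t"))
  }
  ok <- tryCatch({
    writeLines(lines, con = path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    pf_stop("phepart_io_error", sprintf("cannot write to path: %s", path))
  }
  invisible(path)
}

#' Extract one time series from a labelling dataset
#'
#' Returns the post-feeding time points of a (genotype, replicate, variable)
#' series together with the measured t = 0 intercept. Times are strictly
#' increasing. The intercept is the stored t0 value, never extrapolated.
#'
#' @param x a [labeling_data()] object.
#' @param genotype,replicate,variable identifiers of the series.
#' @param require_intercept if `TRUE` (default) a missing t0 row is an
#'   error; tyrosine-labelling and emission series may be extracted with
#'   `FALSE` (emission starts at 0 by definition of cumulative collection).
#' @return A list with `times` (hours, > 0), `values`, `intercept` (value
#'   at t = 0, `NA` if absent and not required), and the identifiers.
#' @export
extract_series <- function(x, genotype, replicate, variable,
                           require_intercept = TRUE) {
  stopifnot(inherits(x, "labeling_data"))
  sel <- x$genotype == genotype & x$replicate == replicate &
    x$variable == variable
  if (!any(sel)) {
    pf_stop("phepart_lookup_error",
            sprintf("no observations for (%s, %s, %s)",
                    genotype, replicate, variable))
  }
  rows <- x[sel, , drop = FALSE]
  rows <- rows[order(rows$time_h), , drop = FALSE]
  at0 <- rows$time_h == 0
  intercept <- if (any(at0)) rows$value[at0][1] else NA_real_
  if (require_intercept && is.na(intercept)) {
    pf_stop("phepart_missing_intercept",
            sprintf("series (%s, %s, %s) has no t = 0 intercept row",
                    genotype, replicate, variable))
  }
  list(times = rows$time_h[!at0], values = rows$value[!at0],
       intercept = intercept, genotype = genotype, replicate = replicate,
       variable = variable)
}

#' @export
print.labeling_data <- function(x, ...) {
  n_series <- nrow(unique(as.data.frame(x)[c("genotype", "replicate",
                                             "variable")]))
  cat(sprintf("<labeling_data> %d observations, %d series, %d genotype(s)\n",
              nrow(x), n_series, length(unique(x$genotype))))
  print(as.data.frame(x), ...)
  invisible(x)
}
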