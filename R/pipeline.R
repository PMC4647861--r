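# End-to-end pipeline: read -> fit -> write tables, report and log.

pf_format_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  df
}

pf_write_tsv <- function(df, path) {
  utils::write.table(pf_format_table(df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

#' Run the full flux-partitioning pipeline
#'
#' Reads (or takes) a labelling dataset, fits the flux model with
#' [phepart()], and -- when `out_dir` is given -- writes the output
#' tables: `fluxes.tsv` (per genotype/replicate/grid-point fluxes with
#' variances), `summary.tsv`, `comparisons.tsv`, a human-readable
#' `report.txt` and a provenance `run.log` (input digest, config digest,
#' seed, package version). All outputs are deterministic functions of
#' (dataset, config, seed): identical inputs give byte-identical files.
#' Warnings raised during fitting (negative fluxes, non-monotone
#' emission) are collected into the report.
#'
#' @param data a [labeling_data()] object or path to a TSV dataset.
#' @param config a [flux_config()] or path to a YAML config file.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return The `phepart` fit, invisibly, with attribute `paths` naming
#'   any files written and attribute `warnings` with collected messages.
#' @export
run_pipeline <- function(data, config = flux_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_flux_config(config)
  if (is.character(data)) data <- read_labeling_data(data, config)
  warnings_seen <- character(0)
  fit <- withCallingHandlers(
    phepart(data, config),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  attr(fit, "warnings") <- warnings_seen
  if (is.null(out_dir)) return(invisible(fit))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flux_rows <- list()
  for (g in fit$genotypes) {
    for (r in names(fit$trajectories[[g]])) {
      tr <- as.data.frame(fit$trajectories[[g]][[r]])
      flux_rows[[length(flux_rows) + 1L]] <-
        cbind(data.frame(genotype = g, replicate = r,
                         stringsAsFactors = FALSE), tr)
    }
  }
  paths <- c(
    fluxes = pf_write_tsv(do.call(rbind, flux_rows),
                          file.path(out_dir, "fluxes.tsv")),
    summary = pf_write_tsv(fit$summary, file.path(out_dir, "summary.tsv")),
    comparisons = pf_write_tsv(
      as.data.frame(fit$comparisons %||%
                      data.frame(comparison = character(0))),
      file.path(out_dir, "comparisons.tsv")))

  report <- report_summary(fit)
  writeLines(report, file.path(out_dir, "report.txt"))
  paths <- c(paths, report = file.path(out_dir, "report.txt"))

  tmp <- tempfile(fileext = ".tsv")
  write_labeling_data(fit$data, tmp)
  data_digest <- unname(tools::md5sum(tmp))
  unlink(tmp)
  cfg <- fit$config
  cfg_str <- paste(vapply(names(cfg), function(nm) {
    sprintf("%s=%s", nm, paste(format(unlist(cfg[[nm]])), collapse = ","))
  }, character(1)), collapse = "; ")
  log_lines <- c(
    sprintf("phepart version: %s", as.character(utils::packageVersion("phepart"))),
    sprintf("input digest (md5): %s", data_digest),
    sprintf("config: %s", cfg_str),
    sprintf("seed: %s", cfg$seed %||% "none"),
    sprintf("stages: read -> trends -> consumption_rate -> fluxes -> %s",
            "variances -> summaries -> comparisons"),
    if (length(warnings_seen)) paste("warning:", warnings_seen) else
      "warnings: none")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  paths <- c(paths, log = file.path(out_dir, "run.log"))
  attr(fit, "paths") <- paths
  invisible(fit)
}

#' Render a human-readable flux report
#'
#' Fixed-template text report of the endpoint fluxes with propagated
#' standard errors, v2/v1 ratios, percent changes relative to control and
#' the genotype comparisons; every number is read from the fitted tables.
#'
#' @param fit a `phepart` fit (e.g. from [run_pipeline()]).
#' @return Character vector of report lines.
#' @export
report_summary <- function(fit) {
  stopifnot(inherits(fit, "phepart"))
  s <- fit$summary
  iend <- length(fit$grid)
  lines <- c(
    "Phenylalanine flux partitioning report",
    sprintf("grid: %g to %g h by %g h; fitting: %s; control: %s",
            fit$grid[1], fit$grid[iend], fit$config$grid_step,
            fit$config$pooling, fit$control),
    "",
    "-- fluxes (nmol/gFW/h, mean +/- propagated s.e.) --")
  for (i in seq_len(nrow(s))) {
    lines <- c(lines,
      sprintf("%s (n=%d):", s$genotype[i], s$n[i]),
      sprintf("  v1(t0) = %.4f +/- %.4f   v1(t_end) = %.4f +/- %.4f",
              s$v1_t0[i], s$v1_t0_se[i], s$v1_tend[i], s$v1_tend_se[i]),
      sprintf("  v2(t0) = %.4f +/- %.4f   v2(t_end) = %.4f +/- %.4f",
              s$v2_t0[i], s$v2_t0_se[i], s$v2_tend[i], s$v2_tend_se[i]),
      sprintf("  vc = %.4f   v2/v1(t_end) = %.4f", s$vc[i], s$ratio_tend[i]))
    if (s$genotype[i] != fit$control) {
      lines <- c(lines, sprintf(
        "  v1 vs control: %.1f%% lower at t0, %.1f%% lower at t_end",
        s$pct_v1_t0[i], s$pct_v1_tend[i]))
    }
  }
  if (!is.null(fit$comparisons) && nrow(fit$comparisons) > 0) {
    lines <- c(lines, "", "-- comparisons --")
    cmp <- as.data.frame(fit$comparisons)
    for (i in seq_len(nrow(cmp))) {
      lines <- c(lines, sprintf(
        "%s | %s%s | stat = %.4f | p_raw = %.6g | p_corrected = %.6g | %s",
        cmp$comparison[i], cmp$quantity[i],
        if (is.na(cmp$time_h[i])) "" else sprintf(" at t=%g h",
                                                  cmp$time_h[i]),
        cmp$stat[i], cmp$p_raw[i], cmp$p_corrected[i], cmp$mode[i]))
    }
  }
  w <- attr(fit, "warnings")
  if (!is.null(w) && length(w) > 0) {
    lines <- c(lines, "", "-- warnings --", paste(" -", unique(w)))
  }
  lines
}
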