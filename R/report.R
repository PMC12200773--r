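#' Assemble the run report
#'
#' Combines the per-category model summaries, convergence diagnostics,
#' exposure distribution, dropped-row accounting and the resolved
#' configuration into one machine-readable bundle plus a human-readable
#' text rendering. The association table has the reporting shape
#' Exposure / Estimate / SE / OR / CI- / CI+ (OR = exp(Estimate); CI bounds
#' are the exponentiated coefficient quantiles). When a category's fit is
#' missing the report is still produced, with the gap listed and the bundle
#' marked incomplete.
#'
#' @param fits Named list of `drought_fit` objects (names are exposure
#'   categories); entries may be missing.
#' @param distribution Exposure-distribution report from
#'   [exposure_distribution()].
#' @param config The resolved [pipeline_config()].
#' @param n_rejects Number of respondents excluded at linkage.
#' @param thresholds Optional [compute_thresholds()] result for provenance.
#' @return A `drought_report` list with elements `association`,
#'   `diagnostics`, `exposure`, `dropped`, `config`, `gaps`, `complete`.
#' @export
build_report <- function(fits, distribution, config, n_rejects = 0L,
                         thresholds = NULL) {
  stopifnot(is.list(fits))
  gaps <- setdiff(.category_names, names(fits))
  fits <- fits[intersect(.category_names, names(fits))]
  association <- purrr::imap_dfr(fits, function(fit, nm) {
    s <- summarize_posterior(fit)
    s <- s[s$term == "exposure", ]
    tibble::tibble(exposure = nm, estimate = s$estimate,
                   se = s$std.error, or = s$or,
                   ci_low = s$conf.low, ci_high = s$conf.high)
  })
  diagnostics <- purrr::imap_dfr(fits, function(fit, nm) {
    dplyr::mutate(compute_diagnostics(fit), exposure = nm, .before = 1)
  })
  dropped <- purrr::imap_dfr(fits, function(fit, nm) {
    tibble::tibble(exposure = nm, n_model = fit$n, n_dropped = fit$n_dropped)
  })
  structure(
    list(association = association,
         diagnostics = diagnostics,
         exposure = distribution,
         dropped = dropped,
         n_rejects = as.integer(n_rejects),
         thresholds = if (!is.null(thresholds)) unclass(thresholds),
         config = unclass(config),
         gaps = gaps,
         complete = length(gaps) == 0L),
    class = "drought_report")
}

#' @export
print.drought_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

report_text <- function(report) {
  assoc <- report$association
  lines <- c(
    "Drought exposure / outcome association report",
    sprintf("seed: %d", report$config$seed),
    sprintf("thresholds: dry <= %.2f, count run >= %d, sum <= %.2f, recent run > %d, top %.0f%%",
            report$config$dry_threshold, report$config$min_run_length,
            report$config$sum_threshold, report$config$recent_long_min_run,
            100 * report$config$extreme_percentile),
    "",
    "Exposure                Estimate      SE      OR     CI-     CI+")
  for (i in seq_len(nrow(assoc))) {
    lines <- c(lines, sprintf("%-22s %9.3f %7.3f %7.3f %7.3f %7.3f",
                              assoc$exposure[i], assoc$estimate[i],
                              assoc$se[i], assoc$or[i], assoc$ci_low[i],
                              assoc$ci_high[i]))
  }
  lines <- c(lines, "",
             sprintf("respondents rejected at linkage: %d", report$n_rejects))
  for (i in seq_len(nrow(report$dropped))) {
    lines <- c(lines, sprintf("  %s: n = %d, dropped (complete case) = %d",
                              report$dropped$exposure[i],
                              report$dropped$n_model[i],
                              report$dropped$n_dropped[i]))
  }
  if (length(report$gaps)) {
    lines <- c(lines, "", paste("MISSING fits:",
                                paste(report$gaps, collapse = ", ")))
  }
  lines
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (machine readable), `report.txt` (human readable)
#' and `association.csv` (the reporting-shaped table).
#'
#' @param report A `drought_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(association = report$association,
         diagnostics = report$diagnostics,
         exposure_totals = report$exposure$totals,
         exposure_combinations = report$exposure$combinations,
         dropped = report$dropped,
         n_rejects = report$n_rejects,
         thresholds = report$thresholds,
         config = report$config,
         gaps = report$gaps,
         complete = report$complete),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(report_text(report), file.path(dir, "report.txt"))
  readr::write_csv(report$association, file.path(dir, "association.csv"))
  invisible(dir)
}
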