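stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Chains the stages simulate (optional) -> exposure -> link -> fit ->
#' report, writing every artefact under `out_dir`:
#' `fixtures/` (when simulating), `exposure.csv`, `rejects.csv`,
#' `thresholds.json`, `fit_<category>.json`, and `report/` with the final
#' bundle plus a resolved-config echo (`config_used.txt`). All randomness
#' derives from `config$seed`, so a rerun with the same configuration
#' reproduces the same artefacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param paths Optional named list with `spei`, `weights`, `cohort` file
#'   paths; when `NULL`, a synthetic fixture bundle is generated first.
#' @param categories Exposure categories to fit (default all four).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the linked cohort, fits, report and paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         paths = NULL,
                         categories = c("slight_to_moderate", "very_dry",
                                        "recent_and_long",
                                        "prolonged_extreme"),
                         quiet = FALSE) {
  config <- validate_config(config)
  categories <- match.arg(categories, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  write_config(config, file.path(out_dir, "config_used.txt"))
  if (is.null(paths)) {
    say("stage simulate: generating fixture bundle (seed ", config$seed, ")")
    fx <- stage("simulate",
                make_fixture_suite(file.path(out_dir, "fixtures"),
                                   seed = config$seed, config = config))
    paths <- fx$paths
  }
  say("stage exposure: reading inputs")
  spei <- stage("exposure", read_spei_grid(paths$spei))
  weights <- stage("exposure", read_cell_weights(paths$weights))
  cohort <- stage("exposure", read_cohort(paths$cohort))
  say("stage link: ", nrow(cohort), " respondents; thresholds: dry <= ",
      config$dry_threshold, ", run >= ", config$min_run_length,
      ", sum <= ", config$sum_threshold, ", recent > ",
      config$recent_long_min_run, ", top ",
      100 * config$extreme_percentile, "%")
  link <- stage("link", link_exposure(cohort, spei, weights, config))
  readr::write_csv(
    dplyr::select(link$linked, "respondent_id", "district_id",
                  "window_end", dplyr::all_of(categories)),
    file.path(out_dir, "exposure.csv"))
  readr::write_csv(link$rejects, file.path(out_dir, "rejects.csv"))
  jsonlite::write_json(unclass(link$thresholds),
                       file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  linked <- stage("fit", derive_outcome(link$linked))
  fits <- list()
  for (cat in categories) {
    say("stage fit: ", cat)
    input <- stage("fit", build_model_input(linked, cat))
    fit <- stage("fit", fit_model(input, chains = config$chains,
                                  draws = config$draws,
                                  warmup = config$warmup,
                                  seed = config$seed))
    fits[[cat]] <- fit
    jsonlite::write_json(
      list(summary = summarize_posterior(fit),
           glance = glance(fit),
           sampler = list(chains = fit$chains, draws = fit$n_draws,
                          warmup = fit$warmup, seed = fit$seed)),
      file.path(out_dir, paste0("fit_", cat, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  say("stage report")
  report <- stage("report",
                  build_report(fits, link$distribution, config,
                               n_rejects = nrow(link$rejects),
                               thresholds = link$thresholds))
  write_report(report, file.path(out_dir, "report"))
  invisible(list(linked = linked, rejects = link$rejects,
                 summaries = link$summaries, thresholds = link$thresholds,
                 fits = fits, report = report, paths = paths,
                 out_dir = out_dir))
}
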