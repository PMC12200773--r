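#' Exposure window for an interview date
#'
#' The exposure window is the closed run of `window_months` calendar months
#' ending the month before the interview month; the interview month itself
#' is excluded (exposure precedes the interview).
#'
#' @param interview_year,interview_month Interview date (vectorised).
#' @param config A [pipeline_config()].
#' @return A tibble with integer columns `window_start` and `window_end`
#'   (month indices, inclusive).
#' @examples
#' w <- window_for_interview(2018, 6)
#' month_label(w$window_start)  # "2014-06"
#' month_label(w$window_end)    # "2018-05"
#' @export
window_for_interview <- function(interview_year, interview_month,
                                 config = pipeline_config()) {
  end <- month_index(interview_year, interview_month) - 1L
  tibble::tibble(window_start = end - config$window_months + 1L,
                 window_end = end)
}

#' Read and validate a cell-to-district coverage weight table
#'
#' @param path CSV with columns `district_id`, `cell_id`, `weight`.
#' @return A tibble with weights renormalised to sum to 1 within each
#'   district.
#' @export
read_cell_weights <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE)
  normalize_weights(w)
}

#' @rdname read_cell_weights
#' @param weights In-memory weight tibble.
#' @export
normalize_weights <- function(weights) {
  stopifnot(all(c("district_id", "cell_id", "weight") %in% names(weights)))
  if (any(weights$weight <= 0)) stop("coverage weights must be positive", call. = FALSE)
  if (anyDuplicated(weights[c("district_id", "cell_id")])) {
    stop("duplicate (district, cell) weight rows", call. = FALSE)
  }
  weights |>
    dplyr::group_by(.data$district_id) |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup()
}

# measures averaged straight across cells; sdi is handled separately
.agg_measures <- c("n_dry", "n_count", "n_sum", "n_both",
                   "cycles_count", "cycles_sum", "cycles_both",
                   "recent_max_run", "n_slight_moderate")

#' Aggregate cell-level drought summaries to districts
#'
#' Each drought measure becomes the coverage-weighted mean across the
#' district's grid cells (fractional month counts are kept as reals). The
#' dryness intensity is averaged only over cells where it is defined, with
#' the weight mass of those cells renormalised; a district where no cell has
#' a defined intensity keeps an undefined (NA) intensity.
#'
#' @param cell_summaries Window summaries with `unit_id` identifying cells,
#'   all for the same window.
#' @param weights Normalised weight tibble ([normalize_weights()]).
#' @return One summary row per district, `unit_id` now the district id.
#' @export
aggregate_district <- function(cell_summaries, weights) {
  weights <- normalize_weights(weights)
  missing <- setdiff(weights$cell_id, cell_summaries$unit_id)
  if (length(missing)) {
    stop("no cell summary for cell(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  joined <- dplyr::inner_join(weights, cell_summaries,
                              by = c(cell_id = "unit_id"))
  joined |>
    dplyr::group_by(.data$district_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(.agg_measures),
                    ~ sum(.x * .data$weight) / sum(.data$weight)),
      sdi = if (all(is.na(.data$sdi))) NA_real_ else
        sum(.data$sdi * .data$weight, na.rm = TRUE) /
        sum(.data$weight[!is.na(.data$sdi)]),
      .groups = "drop"
    ) |>
    dplyr::rename(unit_id = "district_id")
}

#' District-level window summaries from gridded SPEI
#'
#' Computes drought-measure summaries for a set of (district, window) keys,
#' under either aggregation order. `cell_then_average` (default) summarises
#' each grid cell over the window and then coverage-weight-averages the
#' measures; `average_then_index` first builds a weighted-mean district SPEI
#' series and then summarises that series.
#'
#' @param spei_tbl Long cell-level SPEI tibble (`unit_id`, `month`, `spei`).
#' @param weights Cell-to-district weight tibble.
#' @param keys Tibble with columns `district_id`, `window_start`,
#'   `window_end`; one output row per key row.
#' @param config A [pipeline_config()].
#' @return Summary tibble keyed by `district_id`, `window_start`,
#'   `window_end`.
#' @export
district_window_summaries <- function(spei_tbl, weights, keys,
                                      config = pipeline_config()) {
  weights <- normalize_weights(weights)
  keys <- dplyr::distinct(keys, .data$district_id, .data$window_start,
                          .data$window_end)
  unknown <- setdiff(keys$district_id, weights$district_id)
  if (length(unknown)) {
    stop("no coverage weights for district(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (config$aggregation_mode == "cell_then_average") {
    cell_keys <- keys |>
      dplyr::inner_join(weights, by = "district_id",
                        relationship = "many-to-many")
    windows <- dplyr::distinct(
      cell_keys, unit_id = .data$cell_id, .data$window_start,
      .data$window_end)
    cell_sums <- summarize_windows(spei_tbl, windows, config)
    purrr::pmap(
      list(keys$district_id, keys$window_start, keys$window_end),
      function(d, ws, we) {
        w <- weights[weights$district_id == d, , drop = FALSE]
        cs <- cell_sums[cell_sums$window_start == ws &
                          cell_sums$window_end == we &
                          cell_sums$unit_id %in% w$cell_id, , drop = FALSE]
        agg <- aggregate_district(cs, w)
        dplyr::bind_cols(
          tibble::tibble(district_id = d, window_start = ws, window_end = we),
          agg[setdiff(names(agg), "unit_id")])
      }) |>
      dplyr::bind_rows()
  } else {
    district_series <- spei_tbl |>
      dplyr::inner_join(weights, by = c(unit_id = "cell_id"),
                        relationship = "many-to-many") |>
      dplyr::group_by(.data$district_id, .data$month) |>
      dplyr::summarise(spei = sum(.data$spei * .data$weight) /
                         sum(.data$weight), .groups = "drop") |>
      dplyr::rename(unit_id = "district_id")
    windows <- keys |> dplyr::rename(unit_id = "district_id")
    out <- summarize_windows(district_series, windows, config)
    dplyr::rename(out, district_id = "unit_id")
  }
}

#' Attach drought exposure profiles to survey respondents
#'
#' Aligns each respondent's 48-month exposure window to their interview
#' date, computes district-level window summaries from the gridded SPEI,
#' derives sample-relative category cutoffs over the distinct
#' district-window units, and joins the four exposure flags back to the
#' cohort. Respondents whose district has no coverage weights are excluded
#' into a rejects table (with a reason code) rather than failing the run.
#'
#' @param cohort Respondent tibble with `district_id`, `interview_year`,
#'   `interview_month` (see [read_cohort()]).
#' @param spei_tbl Long cell-level SPEI tibble.
#' @param weights Cell-to-district weight tibble.
#' @param config A [pipeline_config()].
#' @return A list: `linked` (cohort rows with exposure flags and window key),
#'   `rejects` (excluded rows with `reject_reason`), `summaries` (the
#'   district-window summary table with flags), `thresholds`, and
#'   `distribution` (the exposure-distribution report).
#' @export
link_exposure <- function(cohort, spei_tbl, weights,
                          config = pipeline_config()) {
  stopifnot(all(c("district_id", "interview_year", "interview_month")
                %in% names(cohort)))
  weights <- normalize_weights(weights)
  known <- cohort$district_id %in% weights$district_id
  rejects <- cohort[!known, , drop = FALSE]
  if (nrow(rejects)) {
    rejects$reject_reason <- "district_without_coverage_weights"
    warning(nrow(rejects), " respondent(s) in districts without coverage ",
            "weights were excluded")
  }
  cohort <- cohort[known, , drop = FALSE]
  cohort <- dplyr::bind_cols(
    cohort,
    window_for_interview(cohort$interview_year, cohort$interview_month,
                         config))
  keys <- dplyr::distinct(cohort, .data$district_id, .data$window_start,
                          .data$window_end)
  summaries <- district_window_summaries(spei_tbl, weights, keys, config)
  thresholds <- compute_thresholds(summaries, config$extreme_percentile)
  summaries <- assign_categories(summaries, thresholds, config)
  linked <- dplyr::left_join(
    cohort, summaries,
    by = c("district_id", "window_start", "window_end"))
  list(linked = linked,
       rejects = rejects,
       summaries = summaries,
       thresholds = thresholds,
       distribution = exposure_distribution(linked))
}
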