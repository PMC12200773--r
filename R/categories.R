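#' Sample-relative category cutoffs
#'
#' The very-dry and prolonged-and-extreme categories are defined relative to
#' the analysed sample: very dry takes the top `extreme_percentile` (default
#' 10%) of units by standardised dryness intensity (the most-negative tail),
#' and prolonged-and-extreme the top decile of months meeting both the count
#' and sum definitions. Cutoffs are empirical quantiles taken as order
#' statistics (`stats::quantile()` type 1, the inverse empirical CDF), so
#' they are invariant when every unit is replicated, and ties at the cutoff
#' are included.
#'
#' The intensity quantile is computed only over units where the intensity is
#' defined (at least one sum-method cycle); units that never experienced a
#' sum-method drought can never be very dry.
#'
#' @param summaries Window-summary tibble (see [summarize_windows()]) with
#'   columns `sdi` and `n_both`.
#' @param extreme_percentile Tail mass in (0, 1).
#' @return An object of class `category_thresholds`: a list with
#'   `sdi_cutoff`, `both_cutoff`, `n_units`, `n_sdi_defined` and
#'   `extreme_percentile`.
#' @export
compute_thresholds <- function(summaries, extreme_percentile = 0.10) {
  stopifnot(all(c("sdi", "n_both") %in% names(summaries)),
            extreme_percentile > 0, extreme_percentile < 1)
  sdi <- summaries$sdi[!is.na(summaries$sdi)]
  n_def <- length(sdi)
  if (n_def == 0L) {
    warning("no unit has a defined dryness intensity; ",
            "the very-dry category will be empty")
    sdi_cutoff <- NA_real_
  } else {
    if (n_def < 10L) {
      warning("only ", n_def, " unit(s) with defined dryness intensity; ",
              "the very-dry cutoff is unstable")
    }
    sdi_cutoff <- unname(quantile(sdi, extreme_percentile, type = 1))
  }
  both_cutoff <- unname(quantile(summaries$n_both, 1 - extreme_percentile,
                                 type = 1))
  structure(
    list(sdi_cutoff = sdi_cutoff,
         both_cutoff = both_cutoff,
         n_units = nrow(summaries),
         n_sdi_defined = n_def,
         extreme_percentile = extreme_percentile),
    class = "category_thresholds"
  )
}

#' @export
print.category_thresholds <- function(x, ...) {
  cat("<category_thresholds>\n")
  cat(sprintf("  very-dry sdi cutoff:     %s (over %d/%d units with sdi)\n",
              format(x$sdi_cutoff), x$n_sdi_defined, x$n_units))
  cat(sprintf("  prolonged n_both cutoff: %s (tail mass %.2f)\n",
              format(x$both_cutoff), x$extreme_percentile))
  invisible(x)
}

#' Assign the four drought exposure categories
#'
#' Adds the four boolean exposure flags to a window-summary table:
#' * `slight_to_moderate` - at least one mild month (-1 < SPEI < 0);
#' * `very_dry` - dryness intensity defined and at or below the sample
#'   cutoff (most negative tail);
#' * `recent_and_long` - longest dry run in the trailing 24 months strictly
#'   greater than 12;
#' * `prolonged_extreme` - a positive number of both-method drought months,
#'   at or above the sample cutoff.
#'
#' Categories are not exclusive: a unit can be in several at once.
#'
#' @param summaries Window-summary tibble; measures may be fractional after
#'   district aggregation and are compared as reals.
#' @param thresholds A [compute_thresholds()] result from the same sample.
#' @param config A [pipeline_config()].
#' @return `summaries` with four logical columns appended.
#' @export
assign_categories <- function(summaries, thresholds,
                              config = pipeline_config()) {
  stopifnot(inherits(thresholds, "category_thresholds"))
  dplyr::mutate(
    summaries,
    slight_to_moderate = .data$n_slight_moderate >= 1,
    very_dry = !is.na(.data$sdi) & !is.na(thresholds$sdi_cutoff) &
      .data$sdi <= thresholds$sdi_cutoff,
    recent_and_long = .data$recent_max_run > config$recent_long_min_run,
    prolonged_extreme = .data$n_both > 0 &
      .data$n_both >= thresholds$both_cutoff
  )
}

#' Exposure distribution report
#'
#' Counts, for a linked cohort, how many respondents fall in each exposure
#' category in total and in each exclusive combination of the four flags
#' (the structure of an exposure upset plot).
#'
#' @param linked Tibble with the four exposure flag columns.
#' @return A list with `totals` (per-category counts) and `combinations`
#'   (one row per observed flag combination with its count).
#' @export
exposure_distribution <- function(linked) {
  flags <- c("slight_to_moderate", "very_dry", "recent_and_long",
             "prolonged_extreme")
  stopifnot(all(flags %in% names(linked)))
  totals <- tibble::tibble(
    category = flags,
    n = unname(vapply(flags, function(f) sum(linked[[f]]), integer(1)))
  )
  combos <- linked |>
    dplyr::count(dplyr::across(dplyr::all_of(flags)), name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  list(totals = totals, combinations = combos, n_respondents = nrow(linked))
}
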