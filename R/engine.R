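#' Flag dry months in an SPEI series
#'
#' A month is dry when its SPEI value is at or below the dry threshold
#' (default -1, i.e. at least "moderately dry" on the standardised scale).
#' Missing months are never dry.
#'
#' @param spei Numeric vector of monthly SPEI values (may contain `NA`).
#' @param dry_threshold Dry cutoff; months with `spei <= dry_threshold` are dry.
#' @return Logical vector the same length as `spei`.
#' @examples
#' flag_dry_months(c(-1, -0.99, 0.3, NA))
#' @export
flag_dry_months <- function(spei, dry_threshold = -1.0) {
  stopifnot(is.numeric(spei), length(dry_threshold) == 1L, dry_threshold < 0)
  out <- !is.na(spei) & spei <= dry_threshold
  out
}

#' Extract maximal runs of consecutive dry months
#'
#' Returns the maximal stretches of consecutive dry months, each with its
#' summed SPEI. Positions are 1-based indices into the input vector; callers
#' working in calendar time add their window's start month.
#'
#' @param dry Logical vector of dry flags (from [flag_dry_months()]).
#' @param spei Optional numeric vector aligned with `dry`; when supplied,
#'   each run carries `sum_spei`, the sum of SPEI over its months.
#' @return A tibble with columns `start`, `end`, `length`, `sum_spei`
#'   (NA when `spei` is not given), one row per maximal run, in order.
#' @export
extract_runs <- function(dry, spei = NULL) {
  stopifnot(is.logical(dry))
  if (!is.null(spei)) stopifnot(length(spei) == length(dry))
  r <- rle(dry)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  sums <- if (is.null(spei)) {
    rep(NA_real_, length(starts))
  } else {
    vapply(seq_along(starts),
           function(i) sum(spei[starts[i]:ends[i]]), numeric(1))
  }
  tibble::tibble(
    start = as.integer(starts),
    end = as.integer(ends),
    length = as.integer(ends - starts + 1L),
    sum_spei = sums
  )
}

run_flags <- function(runs, n) {
  flags <- logical(n)
  for (i in seq_len(nrow(runs))) flags[runs$start[i]:runs$end[i]] <- TRUE
  flags
}

as_cycles <- function(runs, method) {
  tibble::tibble(
    start = runs$start, end = runs$end,
    n_months = runs$length, sum_spei = runs$sum_spei,
    method = method
  )
}

#' Count-method drought detection (duration)
#'
#' A drought by duration is a maximal run of at least `min_run_length`
#' consecutive dry months (default 5). Every month of a qualifying run is a
#' drought month and each qualifying run is one independent drought cycle.
#'
#' @param runs Run tibble from [extract_runs()].
#' @param n Length of the underlying series (for the flag vector).
#' @param min_run_length Minimum qualifying run length.
#' @return A list with `flags` (logical, length `n`) and `cycles`
#'   (tibble of qualifying runs, `method = "count"`).
#' @export
count_method <- function(runs, n, min_run_length = 5L) {
  stopifnot(min_run_length >= 1L)
  qual <- runs[runs$length >= min_run_length, , drop = FALSE]
  list(flags = run_flags(qual, n), cycles = as_cycles(qual, "count"))
}

#' Sum-method drought detection (intensity)
#'
#' A drought by intensity is a maximal run of consecutive dry months whose
#' summed SPEI is at or below `sum_threshold` (default -17.5). The run-length
#' condition of the count method does not apply: a short, very deep run can
#' qualify under the sum method alone. All months of a qualifying run are
#' flagged.
#'
#' @inheritParams count_method
#' @param sum_threshold Summed-SPEI cutoff (negative).
#' @return A list with `flags` and `cycles` (`method = "sum"`).
#' @export
sum_method <- function(runs, n, sum_threshold = -17.5) {
  stopifnot(sum_threshold < 0)
  if (nrow(runs) > 0 && anyNA(runs$sum_spei)) {
    stop("runs must carry sum_spei; call extract_runs() with `spei`",
         call. = FALSE)
  }
  qual <- runs[!is.na(runs$sum_spei) & runs$sum_spei <= sum_threshold, ,
               drop = FALSE]
  list(flags = run_flags(qual, n), cycles = as_cycles(qual, "sum"))
}

#' Months and cycles meeting both drought definitions
#'
#' A month is in a "both" drought when it is flagged by the count method and
#' by the sum method; cycles are the maximal stretches of such months.
#'
#' @param count_flags,sum_flags Logical month flags from [count_method()] and
#'   [sum_method()].
#' @param spei Optional aligned SPEI vector for cycle sums.
#' @return A list with `flags` and `cycles` (`method = "both"`).
#' @export
combine_methods <- function(count_flags, sum_flags, spei = NULL) {
  stopifnot(length(count_flags) == length(sum_flags))
  both <- count_flags & sum_flags
  runs <- extract_runs(both, spei)
  list(flags = both, cycles = as_cycles(runs, "both"))
}

#' Standardised dryness intensity
#'
#' The summed SPEI over all sum-method drought cycles divided by the average
#' cycle duration (total sum-method drought months / number of sum-method
#' cycles). More negative values mean more intense dryness per unit of
#' drought time. Undefined (NA) when there is no sum-method cycle.
#'
#' @param sum_cycles Cycle tibble from [sum_method()].
#' @return A single numeric value (negative), or `NA_real_` when undefined.
#' @examples
#' # one 7-month cycle summing -21: sdi = -21 / (7 / 1) = -3
#' @export
standardized_intensity <- function(sum_cycles) {
  k <- nrow(sum_cycles)
  if (k == 0L) return(NA_real_)
  total_sum <- sum(sum_cycles$sum_spei)
  avg_duration <- sum(sum_cycles$n_months) / k
  total_sum / avg_duration
}

#' Longest dry run inside the trailing sub-window
#'
#' Truncates each maximal dry run to the trailing `recent_subwindow_months`
#' of the window and returns the longest overlap, in months. Used by the
#' recent-and-long category, which requires strictly more than 12 consecutive
#' dry months within the 24 months before data collection.
#'
#' @param dry Logical dry flags for the full window.
#' @param recent_subwindow_months Length of the trailing sub-window.
#' @return Integer: the longest truncated run (0 when none).
#' @export
recent_max_run <- function(dry, recent_subwindow_months = 24L) {
  n <- length(dry)
  stopifnot(n >= recent_subwindow_months)
  recent <- dry[(n - recent_subwindow_months + 1L):n]
  runs <- extract_runs(recent)
  if (nrow(runs) == 0L) 0L else max(runs$length)
}

#' Summarise one exposure window of an SPEI series
#'
#' Computes every drought measure for a single unit over one window: dry
#' months, count/sum/both drought months and cycles, standardised dryness
#' intensity, the longest recent dry run, and the number of mild
#' (slight-to-moderate, -1 < SPEI < 0) months.
#'
#' @param spei Numeric SPEI values covering the window, in month order.
#'   Missing values are allowed (missing months are never dry) but corrupt
#'   values outside \[-10, 10\] are rejected.
#' @param config A [pipeline_config()].
#' @return A one-row tibble (a drought window summary) with columns `n_dry`,
#'   `n_count`, `n_sum`, `n_both`, `cycles_count`, `cycles_sum`,
#'   `cycles_both`, `sdi`, `recent_max_run`, `n_slight_moderate`.
#' @export
summarize_window <- function(spei, config = pipeline_config()) {
  stopifnot(is.numeric(spei), length(spei) >= 1L)
  if (any(abs(spei) > 10, na.rm = TRUE)) {
    stop("SPEI values outside [-10, 10] look corrupt; refusing to summarise",
         call. = FALSE)
  }
  n <- length(spei)
  dry <- flag_dry_months(spei, config$dry_threshold)
  runs <- extract_runs(dry, spei)
  cm <- count_method(runs, n, config$min_run_length)
  sm <- sum_method(runs, n, config$sum_threshold)
  bm <- combine_methods(cm$flags, sm$flags, spei)
  tibble::tibble(
    n_dry = sum(dry),
    n_count = sum(cm$flags),
    n_sum = sum(sm$flags),
    n_both = sum(bm$flags),
    cycles_count = nrow(cm$cycles),
    cycles_sum = nrow(sm$cycles),
    cycles_both = nrow(bm$cycles),
    sdi = standardized_intensity(sm$cycles),
    recent_max_run = as.integer(
      recent_max_run(dry, min(config$recent_subwindow_months, n))),
    n_slight_moderate = sum(!is.na(spei) &
                              spei > config$dry_threshold & spei < 0)
  )
}

#' Summarise many unit-by-window combinations
#'
#' Applies [summarize_window()] to each requested (unit, window) pair of a
#' long SPEI table. Every window must be fully covered by the unit's series;
#' partially covered windows are a hard error naming the unit and the
#' missing months.
#'
#' @param spei_tbl Long tibble with columns `unit_id`, `month` (integer index
#'   from [month_index()]) and `spei`.
#' @param windows Tibble with columns `unit_id`, `window_start`,
#'   `window_end` (inclusive month indices); extra key columns are carried
#'   through.
#' @param config A [pipeline_config()].
#' @return `windows` with the summary columns appended, one row per input row.
#' @export
summarize_windows <- function(spei_tbl, windows, config = pipeline_config()) {
  stopifnot(all(c("unit_id", "month", "spei") %in% names(spei_tbl)),
            all(c("unit_id", "window_start", "window_end") %in% names(windows)))
  series <- split(spei_tbl[c("month", "spei")], spei_tbl$unit_id)
  sums <- purrr::pmap(
    list(windows$unit_id, windows$window_start, windows$window_end),
    function(uid, ws, we) {
      s <- series[[as.character(uid)]]
      if (is.null(s)) stop("no SPEI series for unit ", uid, call. = FALSE)
      wanted <- ws:we
      idx <- match(wanted, s$month)
      if (anyNA(idx)) {
        stop("unit ", uid, " does not cover window months ",
             paste(month_label(wanted[is.na(idx)]), collapse = ", "),
             call. = FALSE)
      }
      summarize_window(s$spei[idx], config)
    })
  dplyr::bind_cols(windows, dplyr::bind_rows(sums))
}
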