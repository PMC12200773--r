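#' Calendar month index
#'
#' Months are handled internally as a single integer index,
#' `year * 12 + (month - 1)`, so that consecutive calendar months differ by
#' exactly 1 and window arithmetic is plain integer arithmetic.
#'
#' @param year Integer calendar year(s).
#' @param month Integer month(s) in 1..12.
#' @return Integer month index (vectorised).
#' @examples
#' month_index(2018, 6) - month_index(2018, 5)  # 1
#' @export
month_index <- function(year, month) {
  stopifnot(all(month >= 1 & month <= 12))
  as.integer(year) * 12L + (as.integer(month) - 1L)
}

#' Convert a month index back to calendar year and month
#'
#' @param index Integer month index as produced by [month_index()].
#' @return A tibble with columns `year` and `month`.
#' @export
index_to_month <- function(index) {
  index <- as.integer(index)
  tibble::tibble(year = index %/% 12L, month = index %% 12L + 1L)
}

#' Format a month index as "YYYY-MM"
#' @param index Integer month index.
#' @return Character vector.
#' @export
month_label <- function(index) {
  ym <- index_to_month(index)
  sprintf("%04d-%02d", ym$year, ym$month)
}
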