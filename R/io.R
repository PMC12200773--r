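#' Read a gridded monthly SPEI table
#'
#' Reads the long-CSV interchange format for cell-level SPEI series: one row
#' per (cell, month) with columns `cell_id`, `year`, `month`, `spei`.
#' Per cell, the time axis must be strictly increasing as stored; calendar
#' gaps are filled with explicit missing values rather than silently
#' dropped, so downstream run detection sees them as non-dry months.
#'
#' @param path CSV file path.
#' @param format Only `"csv_long"` is supported; the long CSV is the
#'   package's canonical SPEI interchange format.
#' @return Long tibble with columns `unit_id`, `month` (integer index from
#'   [month_index()]) and `spei` (`NA` at gap months).
#' @export
read_spei_grid <- function(path, format = "csv_long") {
  format <- match.arg(format, "csv_long")
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("cell_id", "year", "month", "spei")
  if (!all(req %in% names(raw))) {
    stop("SPEI CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  raw$month_index <- month_index(raw$year, raw$month)
  dup <- duplicated(raw[c("cell_id", "month_index")])
  if (any(dup)) {
    stop("duplicate (cell, month) rows: ",
         paste(unique(paste(raw$cell_id[dup], month_label(raw$month_index[dup]))),
               collapse = ", "), call. = FALSE)
  }
  non_mono <- raw |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$month_index, strictly = TRUE),
                     .groups = "drop")
  if (any(!non_mono$ok)) {
    stop("non-monotone time axis for cell(s): ",
         paste(non_mono$cell_id[!non_mono$ok], collapse = ", "),
         call. = FALSE)
  }
  raw |>
    dplyr::group_by(unit_id = .data$cell_id) |>
    dplyr::reframe(month = seq(min(.data$month_index), max(.data$month_index)),
                   spei = .data$spei[match(month, .data$month_index)]) |>
    tibble::as_tibble()
}

#' Write an SPEI table in the long-CSV interchange format
#'
#' @param spei_tbl Long tibble (`unit_id`, `month`, `spei`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spei_grid <- function(spei_tbl, path) {
  ym <- index_to_month(spei_tbl$month)
  readr::write_csv(
    tibble::tibble(cell_id = spei_tbl$unit_id, year = ym$year,
                   month = ym$month, spei = spei_tbl$spei),
    path)
  invisible(path)
}

.cohort_required <- c("respondent_id", "country_id", "district_id",
                      "interview_year", "interview_month", "age",
                      "in_school", "ever_partnered", "poor_household",
                      "sv_lifetime", "sv_recent_raw")

.recent_codes <- c("yes", "no", "not_applicable", "missing")

#' Read a survey cohort table
#'
#' One row per respondent. Binary covariates are coded 0/1 (or TRUE/FALSE),
#' `sv_lifetime` as yes/no, and the recent sexual-violence answer
#' `sv_recent_raw` keeps the survey skip pattern: `yes`, `no`,
#' `not_applicable` (the follow-up was only asked of respondents reporting
#' lifetime violence) or `missing`. An optional positive `weight` column
#' carries survey weights (unit weights assumed otherwise).
#'
#' @param path CSV file path.
#' @return Typed respondent tibble.
#' @export
read_cohort <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(.cohort_required, names(raw))
  if (length(missing_cols)) {
    stop("cohort CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  to_int <- function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " in row(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    v
  }
  to_bool <- function(col) {
    v <- tolower(trimws(raw[[col]]))
    out <- dplyr::case_match(v, c("1", "true", "yes") ~ TRUE,
                             c("0", "false", "no") ~ FALSE,
                             .default = NA)
    bad <- which(is.na(out) & !is.na(v) & v != "na" & v != "")
    if (length(bad)) {
      stop("unknown ", col, " code in row(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    out
  }
  recent <- tolower(trimws(raw$sv_recent_raw))
  recent[is.na(recent) | recent == "" | recent == "na"] <- "missing"
  bad <- which(!recent %in% .recent_codes)
  if (length(bad)) {
    stop("unknown sv_recent_raw code(s) ",
         paste(unique(recent[bad]), collapse = ", "), " in row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    respondent_id = raw$respondent_id,
    country_id = raw$country_id,
    district_id = raw$district_id,
    interview_year = to_int("interview_year"),
    interview_month = to_int("interview_month"),
    age = to_int("age"),
    in_school = to_bool("in_school"),
    ever_partnered = to_bool("ever_partnered"),
    poor_household = to_bool("poor_household"),
    sv_lifetime = to_bool("sv_lifetime"),
    sv_recent_raw = recent,
    weight = if ("weight" %in% names(raw)) as.numeric(raw$weight) else 1
  )
}

#' Write a cohort table
#' @param cohort Respondent tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (col in c("in_school", "ever_partnered", "poor_household")) {
    out[[col]] <- as.integer(out[[col]])
  }
  out$sv_lifetime <- ifelse(cohort$sv_lifetime, "yes", "no")
  readr::write_csv(out, path)
  invisible(path)
}
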