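#' Survey-weighted prevalence by group
#'
#' Weighted prevalence of a binary outcome per group (typically country),
#' with the with-replacement linearised standard error of the weighted
#' ratio estimator and a normal-approximation 95% confidence interval
#' truncated to \[0, 100\]%. With unit weights this reduces exactly to the
#' unweighted proportion. Rows with a missing outcome are excluded per
#' group; boundary estimates (0% or 100%) get a zero SE and a degenerate
#' interval, flagged in the output.
#'
#' @param cohort Respondent tibble; needs the outcome column and, unless
#'   `weight` exists, unit weights are assumed (with a message).
#' @param outcome `"recent"` (uses `sv_recent`, derived on the fly when
#'   absent) or `"lifetime"` (uses `sv_lifetime`).
#' @param by Grouping column, default `"country_id"`.
#' @return Tibble with `n`, `n_pos`, `prevalence`, `se`, `ci_low`,
#'   `ci_high` (all on the percentage scale) and `degenerate`.
#' @examples
#' cohort <- tibble::tibble(country_id = "A", sv_lifetime = c(TRUE, FALSE),
#'                          sv_recent_raw = c("yes", "not_applicable"),
#'                          weight = c(3, 1))
#' weighted_prevalence(cohort, "recent")  # 75%
#' @export
weighted_prevalence <- function(cohort, outcome = c("recent", "lifetime"),
                                by = "country_id") {
  outcome <- match.arg(outcome)
  if (outcome == "recent" && !"sv_recent" %in% names(cohort)) {
    cohort <- derive_outcome(cohort)
  }
  y <- if (outcome == "recent") cohort$sv_recent else
    as.integer(cohort$sv_lifetime)
  if (!"weight" %in% names(cohort)) {
    message("no survey weights found; using unit weights")
    cohort$weight <- 1
  }
  stopifnot(by %in% names(cohort), all(cohort$weight > 0, na.rm = TRUE))
  data <- tibble::tibble(group = cohort[[by]], y = y, w = cohort$weight)
  data <- data[!is.na(data$y), , drop = FALSE]
  empty <- setdiff(unique(cohort[[by]]), unique(data$group))
  if (length(empty)) {
    warning("group(s) with no observed outcome omitted: ",
            paste(empty, collapse = ", "))
  }
  data |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_pos = sum(.data$y),
      p_hat = sum(.data$w * .data$y) / sum(.data$w),
      se_p = sqrt(sum(.data$w^2 * (.data$y - .data$p_hat)^2)) / sum(.data$w),
      .groups = "drop") |>
    dplyr::mutate(
      prevalence = 100 * .data$p_hat,
      se = 100 * .data$se_p,
      ci_low = pmax(.data$prevalence - 1.96 * .data$se, 0),
      ci_high = pmin(.data$prevalence + 1.96 * .data$se, 100),
      degenerate = .data$p_hat %in% c(0, 1)) |>
    dplyr::select(!!by := "group", "n", "n_pos", "prevalence", "se",
                  "ci_low", "ci_high", "degenerate")
}
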