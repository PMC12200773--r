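#' Forest plot of posterior odds ratios
#'
#' @param object A `drought_fit`.
#' @param hierarchy Include `mu`/`sigma` rows (on the exp scale).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot drought_fit
#' @export
autoplot.drought_fit <- function(object, hierarchy = FALSE, ...) {
  s <- summarize_posterior(object, hierarchy = hierarchy)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% credible interval)", y = NULL,
                  title = paste("Exposure:", object$category)) +
    ggplot2::theme_minimal()
}

#' Posterior predictive density overlay
#'
#' Replicate outcome-rate distribution with the observed rate overlaid.
#'
#' @param ppc A [posterior_predictive()] result.
#' @return A ggplot object.
#' @export
plot_ppc_density <- function(ppc) {
  stopifnot(inherits(ppc, "ppc_result"))
  df <- tibble::tibble(x = ppc$replicate_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = ppc$observed_mean, colour = "firebrick") +
    ggplot2::labs(x = "Replicate outcome rate",
                  y = "Density",
                  subtitle = sprintf("observed %.4f, tail prob %.3f",
                                     ppc$observed_mean, ppc$tail_prob)) +
    ggplot2::theme_minimal()
}

#' Exposure category distribution
#'
#' @param distribution An [exposure_distribution()] result.
#' @return A ggplot bar chart of per-category respondent counts.
#' @export
plot_exposure_distribution <- function(distribution) {
  ggplot2::ggplot(distribution$totals,
                  ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "tan3") +
    ggplot2::labs(x = NULL, y = "Respondents exposed",
                  caption = "categories overlap; totals are not exclusive") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Weighted prevalence by group
#'
#' @param prev A [weighted_prevalence()] table.
#' @param by Name of the grouping column in `prev`.
#' @return A ggplot object with point estimates and 95% CIs.
#' @export
plot_prevalence <- function(prev, by = "country_id") {
  ggplot2::ggplot(prev, ggplot2::aes(x = .data$prevalence,
                                     y = .data[[by]])) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "Prevalence (%)", y = NULL) +
    ggplot2::theme_minimal()
}
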