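#' Pipeline configuration
#'
#' Collects every tunable constant of the drought-exposure pipeline in one
#' validated object. Defaults are the study's fixed values: dry months are
#' SPEI <= -1, droughts last at least 5 consecutive dry months (count method)
#' or sum to <= -17.5 (sum method), exposure windows span the 48 months
#' before the interview month, the "recent and long" category needs strictly
#' more than 12 consecutive dry months inside the trailing 24-month
#' sub-window, and the two extreme categories take the top 10% of the sample.
#'
#' @param window_months Length of the exposure window in months.
#' @param recent_subwindow_months Trailing sub-window used by the
#'   recent-and-long category.
#' @param dry_threshold SPEI value at or below which a month is dry.
#' @param min_run_length Minimum dry-run length for the count method.
#' @param sum_threshold Summed-SPEI threshold for the sum method.
#' @param recent_long_min_run Run length the recent-and-long category must
#'   strictly exceed.
#' @param extreme_percentile Tail mass used for the very-dry and
#'   prolonged-and-extreme cutoffs (0.10 = top decile).
#' @param seed Integer seed used for every stochastic stage.
#' @param chains,draws,warmup MCMC sampler settings per chain (`draws` are
#'   post-warmup draws).
#' @param missing_data_policy Only `"complete_case"` is supported: rows with
#'   missing outcome or covariates are dropped and counted.
#' @param aggregation_mode `"cell_then_average"` computes drought measures per
#'   grid cell and then coverage-weight-averages them to districts (default);
#'   `"average_then_index"` averages the SPEI series first and indexes the
#'   district series.
#' @return A `drought_config` list.
#' @examples
#' cfg <- pipeline_config(seed = 7)
#' cfg$sum_threshold
#' @export
pipeline_config <- function(window_months = 48L,
                            recent_subwindow_months = 24L,
                            dry_threshold = -1.0,
                            min_run_length = 5L,
                            sum_threshold = -17.5,
                            recent_long_min_run = 12L,
                            extreme_percentile = 0.10,
                            seed = 1L,
                            chains = 4L,
                            draws = 1500L,
                            warmup = 750L,
                            missing_data_policy = "complete_case",
                            aggregation_mode = c("cell_then_average",
                                                 "average_then_index")) {
  aggregation_mode <- match.arg(aggregation_mode)
  missing_data_policy <- match.arg(missing_data_policy, "complete_case")
  cfg <- list(
    window_months = as.integer(window_months),
    recent_subwindow_months = as.integer(recent_subwindow_months),
    dry_threshold = as.numeric(dry_threshold),
    min_run_length = as.integer(min_run_length),
    sum_threshold = as.numeric(sum_threshold),
    recent_long_min_run = as.integer(recent_long_min_run),
    extreme_percentile = as.numeric(extreme_percentile),
    seed = as.integer(seed),
    chains = as.integer(chains),
    draws = as.integer(draws),
    warmup = as.integer(warmup),
    missing_data_policy = missing_data_policy,
    aggregation_mode = aggregation_mode
  )
  class(cfg) <- "drought_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "drought_config"))
  if (cfg$window_months < cfg$recent_subwindow_months ||
      cfg$recent_subwindow_months < 1L) {
    stop("window_months >= recent_subwindow_months >= 1 is required",
         call. = FALSE)
  }
  if (cfg$min_run_length < 1L) stop("min_run_length must be >= 1", call. = FALSE)
  if (!(cfg$extreme_percentile > 0 && cfg$extreme_percentile < 1)) {
    stop("extreme_percentile must lie strictly in (0, 1)", call. = FALSE)
  }
  if (cfg$sum_threshold >= 0) stop("sum_threshold must be negative", call. = FALSE)
  if (cfg$dry_threshold >= 0) stop("dry_threshold must be negative", call. = FALSE)
  if (cfg$chains < 2L) stop("at least 2 chains are required", call. = FALSE)
  if (cfg$draws < 4L || cfg$warmup < 0L) stop("invalid sampler settings", call. = FALSE)
  cfg
}

#' @export
print.drought_config <- function(x, ...) {
  cat("<drought_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write a plain-text configuration file
#'
#' The on-disk format is one `key: value` pair per line; unknown keys are an
#' error so that typos never silently fall back to defaults.
#'
#' @param path File path.
#' @return `read_config()` returns a `drought_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = ":"), ""))
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- as.list(vals)
  names(args) <- keys
  numeric_keys <- setdiff(allowed, c("missing_data_policy", "aggregation_mode"))
  args[names(args) %in% numeric_keys] <-
    lapply(args[names(args) %in% numeric_keys], as.numeric)
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param config A `drought_config`.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  lines <- vapply(names(unclass(config)), function(nm) {
    sprintf("%s: %s", nm, format(config[[nm]], scientific = FALSE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
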