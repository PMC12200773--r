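#' Simulate SPEI-like gridded monthly series
#'
#' Baseline series are stationary AR(1) Gaussian processes scaled to unit
#' marginal variance (SPEI is a standardised index, so non-drought months
#' are approximately standard normal). Drought episodes are injected by
#' overwriting the scheduled months with independent draws centred at the
#' episode's mean depth (SD 0.3), clipped to be no smaller than -6.
#'
#' @param n_cells Number of grid cells.
#' @param n_months Series length in months.
#' @param ar1 AR(1) coefficient of the baseline, in \[0, 0.95\].
#' @param episodes Tibble of injected droughts with columns `cell_id`,
#'   `start` (month index), `duration` (months) and `mean_depth`
#'   (negative SPEI level). Episodes must not overlap within a cell.
#' @param start_month First month index (default January 2009).
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param depth_sd SD of month-to-month variation around the episode depth.
#' @param bias Optional tibble (`cell_id`, `bias`) of constant per-cell mean
#'   shifts added to the baseline. A genuinely standardised index has no
#'   such shift; a strong positive bias is a synthetic device that creates
#'   cells with no mild-dryness months at all, giving the
#'   slight-to-moderate category variation across the sample.
#' @return A list with `spei` (long tibble: `unit_id`, `month`, `spei`) and
#'   `truth` (episode ledger with the exact injected months).
#' @export
simulate_spei <- function(n_cells, n_months, ar1 = 0.3,
                          episodes = NULL,
                          start_month = month_index(2009, 1),
                          seed = 1L, depth_sd = 0.3, bias = NULL) {
  stopifnot(n_cells >= 1, n_months >= 1, ar1 >= 0, ar1 <= 0.95)
  cell_ids <- sprintf("cell_%03d", seq_len(n_cells))
  months <- start_month + seq_len(n_months) - 1L
  if (is.null(episodes)) {
    episodes <- tibble::tibble(cell_id = character(), start = integer(),
                               duration = integer(), mean_depth = numeric())
  }
  stopifnot(all(c("cell_id", "start", "duration", "mean_depth")
                %in% names(episodes)))
  if (nrow(episodes)) {
    stopifnot(all(episodes$mean_depth < 0),
              all(episodes$cell_id %in% cell_ids),
              all(episodes$start >= start_month),
              all(episodes$start + episodes$duration - 1L <= max(months)))
    ov <- episodes |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::arrange(.data$start, .by_group = TRUE) |>
      dplyr::summarise(
        overlap = dplyr::n() > 1 &&
          any(utils::head(.data$start + .data$duration, -1) >
                utils::tail(.data$start, -1)),
        .groups = "drop")
    if (any(ov$overlap)) {
      stop("overlapping episodes in cell(s): ",
           paste(ov$cell_id[ov$overlap], collapse = ", "), call. = FALSE)
    }
  }
  set.seed(seed)
  series <- purrr::map(cell_ids, function(cid) {
    x <- numeric(n_months)
    x[1] <- rnorm(1)
    if (n_months > 1) {
      innov <- rnorm(n_months - 1, 0, sqrt(1 - ar1^2))
      for (t in 2:n_months) x[t] <- ar1 * x[t - 1] + innov[t - 1]
    }
    x
  })
  names(series) <- cell_ids
  if (!is.null(bias)) {
    stopifnot(all(c("cell_id", "bias") %in% names(bias)),
              all(bias$cell_id %in% cell_ids))
    for (k in seq_len(nrow(bias))) {
      cid <- bias$cell_id[k]
      series[[cid]] <- series[[cid]] + bias$bias[k]
    }
  }
  ledger <- vector("list", nrow(episodes))
  for (k in seq_len(nrow(episodes))) {
    ep <- episodes[k, ]
    pos <- (ep$start - start_month + 1L):(ep$start - start_month + ep$duration)
    depths <- pmax(rnorm(ep$duration, ep$mean_depth, depth_sd), -6)
    series[[ep$cell_id]][pos] <- depths
    ledger[[k]] <- tibble::tibble(cell_id = ep$cell_id,
                                  month = months[pos],
                                  depth = depths)
  }
  spei <- tibble::tibble(
    unit_id = rep(cell_ids, each = n_months),
    month = rep(months, n_cells),
    spei = unlist(series, use.names = FALSE))
  list(spei = spei,
       truth = list(episodes = episodes,
                    episode_months = dplyr::bind_rows(ledger),
                    seed = seed, ar1 = ar1))
}

#' Simulate a multi-country survey cohort with known parameters
#'
#' Respondents are assigned to districts (uniformly at random), inherit the
#' district's four exposure flags, and receive covariates drawn from stated
#' rates (age uniform over 13-24 completed years; binary covariates
#' Bernoulli). The outcome follows the varying-intercept logistic model:
#' country intercepts are Normal(mu, sigma^2) and
#' logit P(recent) = a_c + sum_k beta_k flag_k + gamma' z. The lifetime
#' indicator is recent OR an independent Bernoulli (it exists only to
#' exercise the survey skip pattern), and the raw recent answer is emitted
#' in skip-pattern coding (`not_applicable` when lifetime is no), with a
#' small missingness rate.
#'
#' Default rates emulate the study population: recent prevalence near 10%,
#' school attendance 50%, ever partnered 64%, poor household 40%, lifetime
#' prevalence near 21%, across 14 countries.
#'
#' @param district_flags Tibble with one row per district: `district_id`,
#'   `country_id`, `interview_year`, `interview_month` and the four logical
#'   exposure flags.
#' @param n_respondents Cohort size.
#' @param beta Named numeric: true log-odds effect of each exposure
#'   category. Defaults are presets at the magnitudes of interest.
#' @param gamma Named numeric: covariate effects (age per completed year,
#'   school, partnered, poor).
#' @param mu,sigma Mean and SD of the country intercepts (`sigma = 0` gives
#'   identical intercepts).
#' @param covariate_rates Named rates for the Bernoulli covariates.
#' @param p_lifetime_extra Probability of lifetime-but-not-recent violence.
#' @param p_missing Missingness rate of the raw recent answer.
#' @param seed Integer seed.
#' @return A list with `cohort` (respondent tibble) and `truth` (all
#'   parameters plus the realised country intercepts).
#' @export
simulate_cohort <- function(district_flags,
                            n_respondents = 35309L,
                            beta = c(slight_to_moderate = -0.008,
                                     very_dry = 0.046,
                                     recent_and_long = -0.156,
                                     prolonged_extreme = 0.197),
                            gamma = c(age = 0.03, in_school = -0.1,
                                      ever_partnered = 0.4,
                                      poor_household = 0.1),
                            mu = -3.0, sigma = 0.3,
                            covariate_rates = c(in_school = 0.50,
                                                ever_partnered = 0.64,
                                                poor_household = 0.40),
                            p_lifetime_extra = 0.118,
                            p_missing = 0.0016,
                            seed = 1L) {
  flags <- .category_names
  stopifnot(all(c("district_id", "country_id", "interview_year",
                  "interview_month", flags) %in% names(district_flags)),
            setequal(names(beta), flags),
            setequal(names(gamma), .covariate_names),
            sigma >= 0)
  countries <- sort(unique(district_flags$country_id))
  if (length(countries) < 2L) stop("need >= 2 countries", call. = FALSE)
  set.seed(seed)
  a <- rnorm(length(countries), mu, sigma)
  names(a) <- countries
  d_idx <- sample.int(nrow(district_flags), n_respondents, replace = TRUE)
  d <- district_flags[d_idx, , drop = FALSE]
  age <- sample(13:24, n_respondents, replace = TRUE)
  z <- vapply(c("in_school", "ever_partnered", "poor_household"),
              function(nm) rbinom(n_respondents, 1L, covariate_rates[[nm]]),
              integer(n_respondents))
  eta <- a[d$country_id] +
    as.matrix(dplyr::mutate(d[flags],
                            dplyr::across(dplyr::everything(), as.numeric))) %*%
    beta[flags] +
    gamma[["age"]] * age +
    z %*% gamma[c("in_school", "ever_partnered", "poor_household")]
  pr <- plogis(drop(eta))
  recent <- rbinom(n_respondents, 1L, pr)
  lifetime <- recent == 1L | rbinom(n_respondents, 1L, p_lifetime_extra) == 1L
  raw <- ifelse(lifetime, ifelse(recent == 1L, "yes", "no"), "not_applicable")
  raw[runif(n_respondents) < p_missing] <- "missing"
  cohort <- tibble::tibble(
    respondent_id = sprintf("r%06d", seq_len(n_respondents)),
    country_id = d$country_id,
    district_id = d$district_id,
    interview_year = d$interview_year,
    interview_month = d$interview_month,
    age = age,
    in_school = z[, "in_school"] == 1L,
    ever_partnered = z[, "ever_partnered"] == 1L,
    poor_household = z[, "poor_household"] == 1L,
    sv_lifetime = lifetime,
    sv_recent_raw = raw,
    weight = 1)
  list(cohort = cohort,
       truth = list(beta = as.list(beta), gamma = as.list(gamma),
                    mu = mu, sigma = sigma,
                    country_intercepts = as.list(a),
                    recent_rate = mean(recent),
                    covariate_rates = as.list(covariate_rates),
                    seed = seed))
}

#' Generate an on-disk fixture bundle for the full pipeline
#'
#' Builds a self-consistent synthetic study: gridded SPEI with injected
#' drought episodes, a cell-to-district coverage-weight table, district
#' exposure flags computed by the drought engine itself at each country's
#' interview window, and a cohort whose outcomes follow the association
#' model with known coefficients given those flags. Episode design spreads
#' intensity across countries (one severely dry district and one district
#' with a long recent dry spell per country) so that all four exposure
#' categories occur. Everything is written as plain CSV/JSON.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving every stochastic step.
#' @param n_respondents Cohort size.
#' @param n_countries Number of countries.
#' @param districts_per_country,cells_per_district Spatial layout.
#' @param n_months SPEI series length (from January 2009).
#' @param config A [pipeline_config()].
#' @param ... Passed on to [simulate_cohort()] (true parameter overrides).
#' @return Invisibly, a list with the file `paths`, the in-memory objects
#'   and the ground `truth`.
#' @export
make_fixture_suite <- function(dir, seed = 1L,
                               n_respondents = 5000L,
                               n_countries = 14L,
                               districts_per_country = 3L,
                               cells_per_district = 2L,
                               n_months = 132L,
                               config = pipeline_config(seed = seed),
                               ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stopifnot(n_countries >= 2L, districts_per_country >= 2L)
  countries <- sprintf("country_%02d", seq_len(n_countries))
  layout <- tidyr::expand_grid(
    country_id = countries,
    d = seq_len(districts_per_country)) |>
    dplyr::mutate(district_id = sprintf("%s_d%d", .data$country_id, .data$d))
  cells <- tidyr::expand_grid(
    district_id = layout$district_id,
    k = seq_len(cells_per_district)) |>
    dplyr::mutate(cell_id = sprintf("cell_%03d", dplyr::row_number()))
  w_raw <- rep(seq(1, 2, length.out = cells_per_district),
               times = nrow(layout))
  weights <- normalize_weights(
    tibble::tibble(district_id = cells$district_id,
                   cell_id = cells$cell_id, weight = w_raw))
  # one interview date per country, spread over the study years
  interviews <- tibble::tibble(
    country_id = countries,
    interview_year = 2013L + (seq_len(n_countries) - 1L) %% 7L,
    interview_month = 1L + (seq_len(n_countries) * 5L) %% 12L)
  layout <- dplyr::left_join(layout, interviews, by = "country_id")
  win <- window_for_interview(layout$interview_year, layout$interview_month,
                              config)
  layout <- dplyr::bind_cols(layout, win)
  # injected episodes: district 1 severe & prolonged (depth deepens with the
  # country index so the sample-relative top decile is well defined),
  # district 2 a long dry spell ending at the window end, district 3 baseline
  epi <- layout |>
    dplyr::filter(.data$d %in% c(1L, 2L)) |>
    dplyr::mutate(
      ci = match(.data$country_id, countries),
      start = ifelse(.data$d == 1L, .data$window_end - 40L,
                     .data$window_end - 15L),
      duration = ifelse(.data$d == 1L, 18L, 16L),
      mean_depth = ifelse(.data$d == 1L, -1.8 - 0.1 * .data$ci, -1.6))
  episodes <- epi |>
    dplyr::inner_join(cells, by = "district_id") |>
    dplyr::select("cell_id", "start", "duration", "mean_depth")
  # district 3 of every second country sits in a persistently wet regime:
  # no mild-dryness months, so the slight-to-moderate flag varies
  wet_districts <- layout$district_id[
    layout$d == 3L & (match(layout$country_id, countries) %% 2L == 0L)]
  bias <- cells |>
    dplyr::filter(.data$district_id %in% wet_districts) |>
    dplyr::transmute(cell_id = .data$cell_id, bias = 2.8)
  sim <- simulate_spei(n_cells = nrow(cells), n_months = n_months,
                       ar1 = 0.3, episodes = episodes, seed = seed,
                       bias = bias)
  keys <- dplyr::distinct(layout, .data$district_id, .data$window_start,
                          .data$window_end)
  summaries <- district_window_summaries(sim$spei, weights, keys, config)
  thresholds <- compute_thresholds(summaries, config$extreme_percentile)
  summaries <- assign_categories(summaries, thresholds, config)
  district_flags <- layout |>
    dplyr::left_join(summaries,
                     by = c("district_id", "window_start", "window_end")) |>
    dplyr::select("district_id", "country_id", "interview_year",
                  "interview_month", dplyr::all_of(.category_names))
  cosim <- simulate_cohort(district_flags, n_respondents = n_respondents,
                           seed = seed + 1L, ...)
  paths <- list(spei = file.path(dir, "spei.csv"),
                weights = file.path(dir, "weights.csv"),
                cohort = file.path(dir, "cohort.csv"),
                truth = file.path(dir, "truth.json"))
  write_spei_grid(sim$spei, paths$spei)
  readr::write_csv(weights, paths$weights)
  write_cohort(cosim$cohort, paths$cohort)
  truth <- list(seed = seed,
                episodes = episodes,
                parameters = cosim$truth,
                realized_flags = district_flags)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, spei = sim$spei, weights = weights,
                 cohort = cosim$cohort, district_flags = district_flags,
                 summaries = summaries, thresholds = thresholds,
                 truth = truth))
}
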