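test_that("exposure windows end the month before the interview", {
  w <- window_for_interview(2018, 6)
  expect_equal(month_label(w$window_start), "2014-06")
  expect_equal(month_label(w$window_end), "2018-05")
  w2 <- window_for_interview(2013, 1)
  expect_equal(month_label(w2$window_start), "2009-01")
  expect_equal(month_label(w2$window_end), "2012-12")
  expect_equal(w$window_end - w$window_start + 1L, 48L)
})

mk_cell_summary <- function(ids, n_both, sdi = rep(NA_real_, length(ids))) {
  tibble::tibble(unit_id = ids, n_dry = n_both, n_count = n_both,
                 n_sum = n_both, n_both = n_both,
                 cycles_count = 1, cycles_sum = 1, cycles_both = 1,
                 sdi = sdi, recent_max_run = 0, n_slight_moderate = 0)
}

test_that("district aggregation is a coverage-weighted mean", {
  w1 <- tibble::tibble(district_id = "d1", cell_id = "c1", weight = 1)
  s1 <- mk_cell_summary("c1", 7, -2.5)
  agg1 <- aggregate_district(s1, w1)
  expect_equal(agg1$n_both, 7)
  expect_equal(agg1$sdi, -2.5)
  w2 <- tibble::tibble(district_id = "d1", cell_id = c("c1", "c2"),
                       weight = c(0.5, 0.5))
  s2 <- mk_cell_summary(c("c1", "c2"), c(10, 20))
  expect_equal(aggregate_district(s2, w2)$n_both, 15)
  # sdi averages only over defined cells with renormalised weight
  w3 <- tibble::tibble(district_id = "d1", cell_id = c("c1", "c2"),
                       weight = c(0.9, 0.1))
  s3 <- mk_cell_summary(c("c1", "c2"), c(0, 10),
                        sdi = c(NA_real_, -4.4))
  expect_equal(aggregate_district(s3, w3)$sdi, -4.4)
  s4 <- mk_cell_summary(c("c1", "c2"), c(0, 10))
  expect_true(is.na(aggregate_district(s4, w3)$sdi))
  # missing cell summary names the cell
  expect_error(aggregate_district(s1, w2), "c2")
})

test_that("aggregation commutes with cell replication and stays bounded", {
  w <- tibble::tibble(district_id = "d1", cell_id = c("c1", "c2", "c3"),
                      weight = c(0.5, 0.3, 0.2))
  s <- mk_cell_summary(c("c1", "c2", "c3"), c(4, 9, 30),
                       sdi = c(-1, -6, NA))
  base <- aggregate_district(s, w)
  dup_w <- tibble::tibble(
    district_id = "d1",
    cell_id = c("c1a", "c1b", "c2a", "c2b", "c3a", "c3b"),
    weight = rep(w$weight / 2, each = 2))
  dup_s <- mk_cell_summary(dup_w$cell_id, rep(c(4, 9, 30), each = 2),
                           sdi = rep(c(-1, -6, NA), each = 2))
  dup <- aggregate_district(dup_s, dup_w)
  expect_equal(dup$n_both, base$n_both)
  expect_equal(dup$sdi, base$sdi)
  expect_gte(base$n_both, min(s$n_both))
  expect_lte(base$n_both, max(s$n_both))
})

test_that("both aggregation orders produce consistent summaries", {
  sim <- simulate_spei(
    n_cells = 2, n_months = 60, ar1 = 0,
    episodes = tibble::tibble(cell_id = c("cell_001", "cell_002"),
                              start = month_index(2010, 3),
                              duration = 10L, mean_depth = -2.5),
    seed = 21)
  weights <- tibble::tibble(district_id = "d1",
                            cell_id = c("cell_001", "cell_002"),
                            weight = c(0.5, 0.5))
  keys <- tibble::tibble(district_id = "d1",
                         window_start = month_index(2009, 1),
                         window_end = month_index(2012, 12))
  cfg_a <- pipeline_config(aggregation_mode = "cell_then_average")
  cfg_b <- pipeline_config(aggregation_mode = "average_then_index")
  a <- district_window_summaries(sim$spei, weights, keys, cfg_a)
  b <- district_window_summaries(sim$spei, weights, keys, cfg_b)
  # identical injected droughts in both cells: the 10 drought months
  # survive either aggregation order
  expect_equal(a$n_dry, b$n_dry, tolerance = 0.2)
  expect_gte(a$n_sum, 10)
  expect_gte(b$n_sum, 10)
})

test_that("linkage is a pure function of district and interview month", {
  cfg <- pipeline_config()
  fx <- make_fixture_suite(withr::local_tempdir(), seed = 17,
                           n_respondents = 300, n_countries = 4,
                           config = cfg)
  link <- link_exposure(fx$cohort, fx$spei, fx$weights, cfg)
  flags <- c("slight_to_moderate", "very_dry", "recent_and_long",
             "prolonged_extreme")
  # respondents sharing district and interview month share profiles
  grp <- link$linked |>
    dplyr::group_by(.data$district_id, .data$interview_year,
                    .data$interview_month) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(flags), dplyr::n_distinct),
                     .groups = "drop")
  expect_true(all(as.matrix(grp[flags]) == 1L))
  # permuting cohort rows permutes output rows identically
  perm <- sample(nrow(fx$cohort))
  link2 <- link_exposure(fx$cohort[perm, ], fx$spei, fx$weights, cfg)
  reord <- link2$linked[match(link$linked$respondent_id,
                              link2$linked$respondent_id), ]
  expect_equal(reord$very_dry, link$linked$very_dry)
})

test_that("respondents in unknown districts land in the rejects table", {
  cfg <- pipeline_config()
  fx <- make_fixture_suite(withr::local_tempdir(), seed = 18,
                           n_respondents = 200, n_countries = 3,
                           config = cfg)
  cohort <- fx$cohort
  cohort$district_id[1:5] <- "nowhere"
  expect_warning(
    link <- link_exposure(cohort, fx$spei, fx$weights, cfg), "excluded")
  expect_equal(nrow(link$rejects), 5L)
  expect_equal(unique(link$rejects$reject_reason),
               "district_without_coverage_weights")
  expect_equal(nrow(link$linked) + nrow(link$rejects), nrow(cohort))
  expect_false(any(link$linked$respondent_id %in%
                     link$rejects$respondent_id))
})
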