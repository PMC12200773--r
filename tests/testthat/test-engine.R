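test_that("dry months are exactly those at or below the threshold", {
  expect_equal(flag_dry_months(c(-1.0)), TRUE)
  expect_equal(flag_dry_months(c(-0.99, 0.3)), c(FALSE, FALSE))
  expect_equal(flag_dry_months(c(0.5, -2, -2, -2, -1)),
               c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(flag_dry_months(c(NA, -3)), c(FALSE, TRUE))
})

test_that("run extraction matches the brute-force scanner exhaustively", {
  expect_equal(nrow(extract_runs(rep(FALSE, 6))), 0L)
  r <- extract_runs(c(rep(TRUE, 5), FALSE, TRUE, TRUE))
  expect_equal(r$length, c(5L, 2L))
  # every dry/wet sequence of length 10
  for (code in 0:1023) {
    dry <- as.logical(bitwAnd(bitwShiftR(code, 0:9), 1L))
    got <- extract_runs(dry)
    ref <- bf_runs(dry)
    expect_equal(got$start, ref$start)
    expect_equal(got$end, ref$end)
    # concatenated run months recover all dry months
    expect_equal(sum(got$length), sum(dry))
  }
})

test_that("count method flags whole runs of at least five dry months", {
  n <- 20
  mk <- function(lens, gap = 1) {
    dry <- logical(0)
    for (l in lens) dry <- c(dry, rep(TRUE, l), rep(FALSE, gap))
    length(dry) <- n; dry[is.na(dry)] <- FALSE
    dry
  }
  r5 <- count_method(extract_runs(mk(5)), n)
  expect_equal(sum(r5$flags), 5L)
  expect_equal(nrow(r5$cycles), 1L)
  r4 <- count_method(extract_runs(mk(4)), n)
  expect_equal(sum(r4$flags), 0L)
  expect_equal(nrow(r4$cycles), 0L)
  r637 <- count_method(extract_runs(mk(c(6, 3, 7))), n)
  expect_equal(sum(r637$flags), 13L)
  expect_equal(nrow(r637$cycles), 2L)
})

test_that("sum method is independent of run length", {
  # 6 months at -3: sum -18 qualifies
  s6 <- c(rep(-3, 6), rep(1, 4))
  sm <- sum_method(extract_runs(flag_dry_months(s6), s6), 10)
  expect_equal(sum(sm$flags), 6L)
  expect_equal(nrow(sm$cycles), 1L)
  # 5 months at -1: sum -5 fails the sum method though count qualifies
  s5 <- c(rep(-1, 5), rep(1, 5))
  runs <- extract_runs(flag_dry_months(s5), s5)
  expect_equal(sum(sum_method(runs, 10)$flags), 0L)
  expect_equal(sum(count_method(runs, 10)$flags), 5L)
  # 4 months at -4.5: sum -18 qualifies under sum, not count
  s4 <- c(rep(-4.5, 4), rep(1, 6))
  runs <- extract_runs(flag_dry_months(s4), s4)
  expect_equal(sum(sum_method(runs, 10)$flags), 4L)
  expect_equal(sum(count_method(runs, 10)$flags), 0L)
})

test_that("both-method months are the count/sum intersection", {
  s <- c(rep(-3, 6), rep(1, 4))
  runs <- extract_runs(flag_dry_months(s), s)
  cm <- count_method(runs, 10); sm <- sum_method(runs, 10)
  bm <- combine_methods(cm$flags, sm$flags, s)
  expect_equal(sum(bm$flags), 6L)
  expect_equal(nrow(bm$cycles), 1L)
  # disjoint: deep-short run (sum only) next to shallow-long run (count only)
  s2 <- c(rep(-4.5, 4), 1, rep(-1.2, 5), rep(1, 2))
  runs2 <- extract_runs(flag_dry_months(s2), s2)
  bm2 <- combine_methods(count_method(runs2, 12)$flags,
                         sum_method(runs2, 12)$flags, s2)
  expect_equal(sum(bm2$flags), 0L)
})

test_that("standardised dryness intensity follows the stated formula", {
  one <- tibble::tibble(start = 1L, end = 7L, n_months = 7L,
                        sum_spei = -21, method = "sum")
  expect_equal(standardized_intensity(one), -3.0)
  two <- tibble::tibble(start = c(1L, 20L), end = c(8L, 31L),
                        n_months = c(8L, 12L), sum_spei = c(-20, -24),
                        method = "sum")
  # (-44) / (20 months / 2 cycles) = -4.4
  expect_equal(standardized_intensity(two), -4.4)
  none <- two[0, ]
  expect_true(is.na(standardized_intensity(none)))
})

test_that("recent run length is the longest overlap with the sub-window", {
  w <- 48
  mk_tail <- function(k) c(rep(FALSE, w - k), rep(TRUE, k))
  expect_equal(recent_max_run(mk_tail(13)), 13L)
  expect_equal(recent_max_run(mk_tail(12)), 12L)
  # 20-month run at months 15..34 of a 48-month window: the trailing
  # 24-month sub-window covers months 25..48, so the overlap is 10
  dry <- rep(FALSE, w)
  dry[15:34] <- TRUE
  expect_equal(recent_max_run(dry), 10L)
})

test_that("window summaries satisfy their internal invariants", {
  cfg <- pipeline_config()
  calm <- summarize_window(rep(0.5, 48), cfg)
  expect_equal(calm$n_dry, 0L)
  expect_equal(calm$cycles_sum, 0L)
  expect_true(is.na(calm$sdi))
  expect_equal(calm$n_slight_moderate, 0L)
  # mild band is strictly between -1 and 0
  mild <- summarize_window(c(-1, -0.5, -0.0001, 0, 0.2, rep(1, 43)), cfg)
  expect_equal(mild$n_slight_moderate, 2L)
  expect_equal(mild$n_dry, 1L)
  for (seed in 1:60) {
    s <- random_spei(48, seed)
    sm <- summarize_window(s, cfg)
    expect_lte(sm$n_both, min(sm$n_count, sm$n_sum))
    expect_lte(sm$n_count, sm$n_dry)
    expect_lte(sm$n_sum, sm$n_dry)
    expect_lte(sm$n_dry, 48)
    if (sm$n_count == 0) expect_equal(sm$cycles_count, 0L)
    if (sm$n_sum == 0) expect_equal(sm$cycles_sum, 0L)
    expect_equal(is.na(sm$sdi), sm$cycles_sum == 0)
    if (!is.na(sm$sdi)) expect_lt(sm$sdi, 0)
    ref <- bf_measures(s)
    expect_equal(sm$n_count, ref$n_count)
    expect_equal(sm$n_sum, ref$n_sum)
    expect_equal(sm$n_both, ref$n_both)
  }
})

test_that("corrupt SPEI values are rejected", {
  expect_error(summarize_window(c(rep(0, 47), 12)), "corrupt")
})

test_that("measures respond monotonically to perturbations", {
  cfg <- pipeline_config()
  base <- c(rep(-1.5, 6), rep(1, 42))
  longer <- c(rep(-1.5, 7), rep(1, 41))
  expect_gte(summarize_window(longer, cfg)$n_count,
             summarize_window(base, cfg)$n_count)
  # deepening any month can only push sdi down (or leave it defined equal)
  deep <- c(rep(-3.5, 6), rep(1, 42))
  expect_lte(summarize_window(deep, cfg)$sdi,
             summarize_window(c(rep(-3, 6), rep(1, 42)), cfg)$sdi)
})

test_that("summarize_windows demands full coverage and names the gap", {
  spei <- tibble::tibble(unit_id = "u1",
                         month = month_index(2014, 1) + 0:47,
                         spei = 0.3)
  win <- tibble::tibble(unit_id = "u1",
                        window_start = month_index(2014, 1),
                        window_end = month_index(2018, 6))
  expect_error(summarize_windows(spei, win), "u1.*2018")
  ok <- tibble::tibble(unit_id = "u1",
                       window_start = month_index(2014, 1),
                       window_end = month_index(2017, 12))
  out <- summarize_windows(spei, ok)
  expect_equal(out$n_dry, 0L)
})
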