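# Brute-force maximal-run scanner: the independent oracle for run extraction.
# Walks the flag vector once, opening a run at each FALSE->TRUE transition.
bf_runs <- function(dry) {
  starts <- integer(0); ends <- integer(0)
  open <- FALSE
  for (i in seq_along(dry)) {
    if (dry[i] && !open) { starts <- c(starts, i); open <- TRUE }
    if (!dry[i] && open) { ends <- c(ends, i - 1L); open <- FALSE }
  }
  if (open) ends <- c(ends, length(dry))
  data.frame(start = starts, end = ends, length = ends - starts + 1L)
}

# Brute-force window measures via the scanner (independent of the engine).
bf_measures <- function(spei, dry_threshold = -1, min_run = 5,
                        sum_threshold = -17.5) {
  dry <- !is.na(spei) & spei <= dry_threshold
  runs <- bf_runs(dry)
  runs$sum <- vapply(seq_len(nrow(runs)),
                     function(i) sum(spei[runs$start[i]:runs$end[i]]),
                     numeric(1))
  cnt <- runs[runs$length >= min_run, , drop = FALSE]
  sm <- runs[runs$sum <= sum_threshold, , drop = FALSE]
  in_any <- function(q) {
    f <- logical(length(spei))
    for (i in seq_len(nrow(q))) f[q$start[i]:q$end[i]] <- TRUE
    f
  }
  cflag <- in_any(cnt); sflag <- in_any(sm)
  list(n_dry = sum(dry), n_count = sum(cflag), n_sum = sum(sflag),
       n_both = sum(cflag & sflag),
       cycles_count = nrow(cnt), cycles_sum = nrow(sm))
}

# A small district grid where only the focal category varies, for model tests.
test_districts <- function(n_countries = 6L, per_country = 2L,
                           focal = "prolonged_extreme") {
  d <- tibble::tibble(
    district_id = sprintf("d%02d", seq_len(n_countries * per_country)),
    country_id = rep(sprintf("c%02d", seq_len(n_countries)),
                     each = per_country),
    interview_year = 2018L, interview_month = 6L,
    slight_to_moderate = FALSE, very_dry = FALSE,
    recent_and_long = FALSE, prolonged_extreme = FALSE)
  d[[focal]] <- rep(c(TRUE, FALSE), length.out = nrow(d))
  d
}

# Simulated cohort with flags joined back on, ready for build_model_input().
sim_linked_cohort <- function(districts, beta_focal, n, seed,
                              focal = "prolonged_extreme", mu = -2.2,
                              sigma = 0.3, ...) {
  beta <- c(slight_to_moderate = 0, very_dry = 0, recent_and_long = 0,
            prolonged_extreme = 0)
  beta[focal] <- beta_focal
  sim <- simulate_cohort(districts, n_respondents = n, beta = beta,
                         mu = mu, sigma = sigma, seed = seed, ...)
  flags <- c("slight_to_moderate", "very_dry", "recent_and_long",
             "prolonged_extreme")
  linked <- dplyr::left_join(derive_outcome(sim$cohort),
                             districts[c("district_id", flags)],
                             by = "district_id")
  attr(linked, "truth") <- sim$truth
  linked
}

# A drought_fit whose draws are fixed, for testing the reporting transform.
constant_fit <- function(estimates, draws = 8L, chains = 2L) {
  terms <- names(estimates)
  arr <- array(rep(estimates, each = draws * chains),
               dim = c(draws, chains, length(terms)),
               dimnames = list(NULL, NULL, terms))
  structure(list(draws = arr, category = "test", n = 0L, n_dropped = 0L,
                 n_countries = 2L, country_levels = c("a", "b"),
                 chains = chains, n_draws = draws, warmup = 0L, seed = 1L,
                 prior_sd = 1, sigma_prior_sd = 1),
            class = "drought_fit")
}

random_spei <- function(n, seed) {
  set.seed(seed)
  # mixture baseline: occasional deep spells so all measures activate
  x <- rnorm(n)
  spell <- rbinom(1, 1, 0.7)
  if (spell == 1) {
    len <- sample(3:14, 1)
    at <- sample(seq_len(n - len), 1)
    x[at:(at + len - 1)] <- rnorm(len, -2.2, 0.6)
  }
  x
}
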