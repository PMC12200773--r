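test_that("outcome derivation honours the skip pattern", {
  cohort <- tibble::tibble(
    sv_lifetime = c(TRUE, TRUE, FALSE, TRUE),
    sv_recent_raw = c("yes", "no", "not_applicable", "missing"))
  out <- derive_outcome(cohort)
  expect_equal(out$sv_recent, c(1L, 0L, 0L, NA_integer_))
  bad <- tibble::tibble(sv_lifetime = TRUE,
                        sv_recent_raw = "not_applicable")
  expect_error(derive_outcome(bad), "not_applicable")
  bad2 <- tibble::tibble(sv_lifetime = FALSE, sv_recent_raw = "yes")
  expect_error(derive_outcome(bad2), "sv_lifetime = no")
})

test_that("model input is assembled for the focal category only", {
  districts <- test_districts(focal = "very_dry")
  linked <- sim_linked_cohort(districts, beta_focal = 0.3, n = 600,
                              seed = 9, focal = "very_dry")
  inp <- build_model_input(linked, "very_dry")
  expect_equal(inp$X[, "exposure"],
               as.numeric(linked$very_dry[stats::complete.cases(
                 linked[c("sv_recent", "very_dry", "age", "in_school",
                          "ever_partnered", "poor_household",
                          "country_id")])]))
  # bookkeeping identity: model rows + dropped rows = cohort rows
  expect_equal(inp$n + inp$n_dropped, nrow(linked))
  expect_equal(inp$n_dropped, sum(is.na(linked$sv_recent)))
})

test_that("degenerate designs are rejected", {
  districts <- test_districts()
  linked <- sim_linked_cohort(districts, 0.2, n = 300, seed = 10)
  one_country <- dplyr::filter(linked, .data$country_id == "c01")
  expect_error(build_model_input(one_country, "prolonged_extreme"),
               "2 countries")
  linked$very_dry <- FALSE
  expect_error(build_model_input(linked, "very_dry"), "no variation")
})

test_that("posterior summary applies the inverse-link transform", {
  fit <- suppressWarnings(constant_fit(c(exposure = 0.197)))
  s <- suppressWarnings(summarize_posterior(fit))
  expect_equal(round(s$or[s$term == "exposure"], 3), 1.218)
  # degenerate draws at zero give OR exactly 1 with a point interval
  f0 <- constant_fit(c(exposure = 0))
  s0 <- suppressWarnings(summarize_posterior(f0))
  expect_equal(s0$or, 1)
  expect_equal(s0$conf.low, 1)
  expect_equal(s0$conf.high, 1)
})

test_that("OR intervals bracket the OR point estimate", {
  set.seed(14)
  draws <- array(rnorm(4000, 0.046, 0.002), dim = c(1000, 4, 1),
                 dimnames = list(NULL, NULL, "exposure"))
  fit <- constant_fit(c(exposure = 0))
  fit$draws <- draws
  s <- summarize_posterior(fit)
  expect_equal(s$or, 1.047, tolerance = 1e-3)
  expect_lte(s$conf.low, s$or)
  expect_gte(s$conf.high, s$or)
})

test_that("fits recover known parameters and are seed-deterministic", {
  districts <- test_districts()
  linked <- sim_linked_cohort(districts, beta_focal = 0.4, n = 4000,
                              seed = 15)
  inp <- build_model_input(linked, "prolonged_extreme")
  fit <- fit_model(inp, chains = 2, draws = 800, warmup = 500, seed = 2)
  s <- tidy(fit)
  beta_hat <- s$estimate[s$term == "exposure"]
  expect_lt(abs(beta_hat - 0.4), 0.2)
  # credible interval brackets for all rows
  expect_true(all(s$conf.low <= s$or & s$or <= s$conf.high))
  fit2 <- fit_model(inp, chains = 2, draws = 800, warmup = 500, seed = 2)
  expect_identical(fit$draws, fit2$draws)
  g <- glance(fit)
  expect_equal(g$n, inp$n)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("negating the exposure coding negates the coefficient", {
  districts <- test_districts()
  linked <- sim_linked_cohort(districts, beta_focal = 0.5, n = 3000,
                              seed = 16)
  inp <- build_model_input(linked, "prolonged_extreme")
  flipped <- linked
  flipped$prolonged_extreme <- !flipped$prolonged_extreme
  inp_f <- build_model_input(flipped, "prolonged_extreme")
  f1 <- fit_model(inp, chains = 2, draws = 800, warmup = 500, seed = 3)
  f2 <- fit_model(inp_f, chains = 2, draws = 800, warmup = 500, seed = 3)
  b1 <- mean(f1$draws[, , "exposure"])
  b2 <- mean(f2$draws[, , "exposure"])
  expect_lt(abs(b1 + b2), 0.1)
})

test_that("posterior means agree with an independent JAGS fit", {
  districts <- test_districts(n_countries = 4)
  linked <- sim_linked_cohort(districts, beta_focal = 0.5, n = 1200,
                              seed = 5, mu = -1.5)
  inp <- build_model_input(linked, "prolonged_extreme")
  fit <- fit_model(inp, chains = 2, draws = 1500, warmup = 600, seed = 2)
  s <- tidy(fit)
  mine <- s$estimate[s$term == "exposure"]
  Xc <- sweep(inp$X, 2, colMeans(inp$X))
  model_str <- "model{
    for (i in 1:n) { y[i] ~ dbern(ilogit(a[cc[i]] + inprod(X[i,], b))) }
    for (c in 1:C) { a[c] ~ dnorm(mu, 1 / (sigma * sigma)) }
    for (j in 1:p) { b[j] ~ dnorm(0, 1) }
    mu ~ dnorm(0, 1)
    sigma ~ dnorm(0, 1) T(0,)
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = inp$y, X = Xc, cc = inp$country, n = inp$n,
                C = length(inp$country_levels), p = ncol(inp$X)),
    n.chains = 2, n.adapt = 500, quiet = TRUE)
  js <- rjags::coda.samples(jm, "b", n.iter = 2000)
  theirs <- summary(js)$statistics["b[1]", "Mean"]
  expect_lt(abs(mine - theirs), 0.05)
})
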