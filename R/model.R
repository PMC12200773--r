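#' Derive the recent sexual-violence outcome from the skip pattern
#'
#' The follow-up question about the previous 12 months is only asked of
#' respondents who reported lifetime sexual violence, so the raw code
#' `not_applicable` (lifetime = no) means no recent violence and is recoded
#' to 0. `missing` stays missing and is dropped later under the
#' complete-case policy. A `not_applicable` or `yes` paired with an
#' inconsistent lifetime answer is a hard error.
#'
#' @param cohort Respondent tibble with `sv_lifetime` and `sv_recent_raw`.
#' @return `cohort` with an integer `sv_recent` column (0/1/NA).
#' @export
derive_outcome <- function(cohort) {
  stopifnot(all(c("sv_lifetime", "sv_recent_raw") %in% names(cohort)))
  raw <- cohort$sv_recent_raw
  life <- cohort$sv_lifetime
  bad_na <- which(raw == "not_applicable" & life)
  if (length(bad_na)) {
    stop("sv_recent_raw = not_applicable but sv_lifetime = yes in row(s): ",
         paste(head(bad_na, 5), collapse = ", "), call. = FALSE)
  }
  bad_yes <- which(raw == "yes" & !life)
  if (length(bad_yes)) {
    stop("sv_recent_raw = yes but sv_lifetime = no in row(s): ",
         paste(head(bad_yes, 5), collapse = ", "), call. = FALSE)
  }
  cohort$sv_recent <- dplyr::case_match(raw,
                                        "yes" ~ 1L,
                                        "no" ~ 0L,
                                        "not_applicable" ~ 0L,
                                        "missing" ~ NA_integer_)
  cohort
}

.category_names <- c("slight_to_moderate", "very_dry", "recent_and_long",
                     "prolonged_extreme")
.covariate_names <- c("age", "in_school", "ever_partnered", "poor_household")

#' Assemble the model input for one exposure category
#'
#' One model is fitted per exposure category, with a single binary exposure
#' indicator (the implicit reference group being everyone not in that
#' category) and the four sociodemographic covariates. Rows with a missing
#' outcome or covariate are dropped (complete case) and counted.
#'
#' @param linked Linked cohort (from [link_exposure()]) with `sv_recent`
#'   already derived (see [derive_outcome()]).
#' @param category One of `"slight_to_moderate"`, `"very_dry"`,
#'   `"recent_and_long"`, `"prolonged_extreme"`.
#' @param standardize_age Centre and scale age before fitting (off by
#'   default; age enters in raw completed years).
#' @return A `drought_model_input` list: outcome `y`, design matrix `X`
#'   (exposure first, then covariates), country index, level labels and
#'   dropped-row accounting.
#' @export
build_model_input <- function(linked, category, standardize_age = FALSE) {
  category <- match.arg(category, .category_names)
  if (!"sv_recent" %in% names(linked)) linked <- derive_outcome(linked)
  need <- c("sv_recent", category, .covariate_names, "country_id")
  missing_cols <- setdiff(need, names(linked))
  if (length(missing_cols)) {
    stop("linked cohort lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(linked[need])
  data <- linked[complete, , drop = FALSE]
  n_dropped <- sum(!complete)
  countries <- sort(unique(data$country_id))
  if (length(countries) < 2L) {
    stop("varying intercepts need >= 2 countries, got ",
         length(countries), call. = FALSE)
  }
  x <- as.numeric(data[[category]])
  if (all(x == 0) || all(x == 1)) {
    stop("exposure category '", category,
         "' has no variation; model is non-identifiable", call. = FALSE)
  }
  age <- as.numeric(data$age)
  if (standardize_age) age <- as.numeric(scale(age))
  X <- cbind(exposure = x,
             age = age,
             in_school = as.numeric(data$in_school),
             ever_partnered = as.numeric(data$ever_partnered),
             poor_household = as.numeric(data$poor_household))
  structure(
    list(y = as.integer(data$sv_recent),
         X = X,
         country = match(data$country_id, countries),
         country_levels = countries,
         category = category,
         n = nrow(data),
         n_dropped = n_dropped,
         standardize_age = standardize_age),
    class = "drought_model_input")
}

#' Fit the varying-intercept Bayesian logistic model
#'
#' Posterior sampling for
#' \deqn{\mathrm{logit}\,P(y_i = 1) = a_{c[i]} + \beta x_i + \gamma' z_i,
#'   \quad a_c \sim N(\mu, \sigma^2),}
#' with weakly informative priors: coefficients and \eqn{\mu} are
#' \eqn{N(0, 1)} and \eqn{\sigma} is Half-Normal(1). Sampling uses an
#' adaptive Metropolis-within-Gibbs scheme (random-walk updates per
#' coefficient and per country intercept, a conjugate Gibbs draw for
#' \eqn{\mu}, and a log-scale step for \eqn{\sigma}); proposal scales adapt
#' during warmup only, so the kept draws come from a fixed kernel. Chains
#' start from jittered initial values and run sequentially under one seed,
#' making fits exactly reproducible.
#'
#' Predictors are mean-centred internally before sampling (coefficients are
#' unaffected; without centring, intercepts and the age slope are almost
#' perfectly correlated and coordinate-wise updates cannot mix). The
#' `N(0, 1)` prior on intercepts applies to the centred parameterisation;
#' stored intercept draws are shifted back to the raw-covariate scale.
#'
#' @param input A [build_model_input()] result.
#' @param chains Number of chains (>= 2).
#' @param draws Post-warmup draws kept per chain.
#' @param warmup Warmup (adaptation) iterations per chain, discarded.
#' @param seed Integer seed.
#' @param prior_sd Prior SD for coefficients and \eqn{\mu}.
#' @param sigma_prior_sd Scale of the Half-Normal prior on \eqn{\sigma}.
#' @return A `drought_fit` object holding a `draws` array
#'   (iterations x chains x parameters) and sampler metadata.
#' @export
fit_model <- function(input, chains = 4L, draws = 1500L, warmup = 750L,
                      seed = 1L, prior_sd = 1.0, sigma_prior_sd = 1.0) {
  stopifnot(inherits(input, "drought_model_input"), chains >= 2L)
  p <- ncol(input$X)
  C <- length(input$country_levels)
  par_names <- c(colnames(input$X),
                 paste0("a[", input$country_levels, "]"),
                 "mu", "sigma")
  base_intercept <- qlogis(min(max(mean(input$y), 0.01), 0.99))
  arr <- array(NA_real_, dim = c(draws, chains, length(par_names)),
               dimnames = list(NULL, NULL, par_names))
  col_means <- colMeans(input$X)
  Xc <- sweep(input$X, 2, col_means)
  set.seed(seed)
  for (ch in seq_len(chains)) {
    init <- c(rnorm(p, 0, 0.1),
              base_intercept + rnorm(C, 0, 0.2),
              base_intercept + rnorm(1, 0, 0.2),
              abs(rnorm(1, 0.5, 0.1)))
    arr[, ch, ] <- mwg_logistic(input$y, Xc,
                                as.integer(input$country - 1L), C,
                                n_iter = warmup + draws, n_warmup = warmup,
                                init = init, prior_sd = prior_sd,
                                sigma_prior_sd = sigma_prior_sd)
  }
  # intercept draws back to the raw-covariate scale
  shift <- matrix(arr[, , seq_len(p), drop = FALSE],
                  ncol = p)[, seq_len(p), drop = FALSE] %*% col_means
  shift <- array(shift, dim = c(draws, chains))
  for (k in c(paste0("a[", input$country_levels, "]"), "mu")) {
    arr[, , k] <- arr[, , k] - shift
  }
  structure(
    list(draws = arr,
         category = input$category,
         n = input$n,
         n_dropped = input$n_dropped,
         n_countries = C,
         country_levels = input$country_levels,
         chains = chains,
         n_draws = draws,
         warmup = warmup,
         seed = seed,
         prior_sd = prior_sd,
         sigma_prior_sd = sigma_prior_sd),
    class = "drought_fit")
}

#' @export
print.drought_fit <- function(x, ...) {
  cat(sprintf("<drought_fit> category=%s, n=%d (%d dropped), %d countries\n",
              x$category, x$n, x$n_dropped, x$n_countries))
  cat(sprintf("  %d chains x %d draws (warmup %d), seed %d\n",
              x$chains, x$n_draws, x$warmup, x$seed))
  print(summarize_posterior(x), n = Inf)
  invisible(x)
}

#' Posterior coefficient summary
#'
#' One row per reported parameter: the posterior mean of the log-odds
#' coefficient ("Estimate"), its posterior SD ("SE"), the posterior median,
#' the odds ratio `exp(estimate)`, the 95% credible interval mapped to the
#' OR scale (`exp` of the 2.5% and 97.5% coefficient quantiles), and
#' convergence diagnostics (split-Rhat, bulk ESS). The OR columns are
#' meaningful for the regression coefficients; they are reported for all
#' rows for completeness.
#'
#' @param fit A `drought_fit`.
#' @param hierarchy Include the hyperparameters `mu` and `sigma` (default)
#'   in addition to the coefficients; country intercepts are never in the
#'   headline table.
#' @return A tibble with columns `term`, `estimate`, `median`, `std.error`,
#'   `or`, `conf.low`, `conf.high`, `rhat`, `ess`.
#' @export
summarize_posterior <- function(fit, hierarchy = TRUE) {
  stopifnot(inherits(fit, "drought_fit"))
  terms <- dimnames(fit$draws)[[3]]
  keep <- terms[!grepl("^a\\[", terms)]
  if (!hierarchy) keep <- setdiff(keep, c("mu", "sigma"))
  rows <- purrr::map(keep, function(tm) {
    m <- fit$draws[, , tm, drop = TRUE]
    v <- as.vector(m)
    q <- quantile(v, c(0.025, 0.975), names = FALSE)
    tibble::tibble(
      term = tm,
      estimate = mean(v),
      median = median(v),
      std.error = sd(v),
      or = exp(mean(v)),
      conf.low = exp(q[1]),
      conf.high = exp(q[2]),
      rhat = split_rhat(m),
      ess = bulk_ess(m))
  })
  dplyr::bind_rows(rows)
}

#' @rdname summarize_posterior
#' @param x A `drought_fit`.
#' @param ... Unused.
#' @method tidy drought_fit
#' @export
tidy.drought_fit <- function(x, ...) summarize_posterior(x)

#' One-row fit overview
#'
#' @param x A `drought_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, sampler settings, worst-case
#'   convergence diagnostics across reported parameters, and whether the
#'   fit passes the convergence gates (Rhat <= 1.01, bulk ESS >= 400).
#' @method glance drought_fit
#' @export
glance.drought_fit <- function(x, ...) {
  s <- summarize_posterior(x)
  tibble::tibble(
    category = x$category,
    n = x$n,
    n_dropped = x$n_dropped,
    n_countries = x$n_countries,
    chains = x$chains,
    total_draws = x$chains * x$n_draws,
    max_rhat = max(s$rhat, na.rm = TRUE),
    min_ess = min(s$ess, na.rm = TRUE),
    converged = max(s$rhat, na.rm = TRUE) <= 1.01 &
      min(s$ess, na.rm = TRUE) >= 400)
}
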