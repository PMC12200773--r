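#' Split-chain potential scale reduction factor (Rhat)
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed over the resulting half-chains, so that a trending
#' chain is detected even when all chains trend together. Values near 1
#' indicate convergence; constant (zero-variance) draws give `NA` with a
#' warning since the estimator is undefined there.
#'
#' @param draws Numeric matrix, iterations x chains.
#' @return A single numeric Rhat value.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  check_chain_shape(draws)
  half <- split_chains(draws)
  n <- nrow(half)
  means <- colMeans(half)
  vars <- apply(half, 2, var)
  w <- mean(vars)
  if (!is.finite(w) || w == 0) {
    warning("zero within-chain variance; Rhat undefined")
    return(NA_real_)
  }
  b <- n * var(means)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Bulk effective sample size
#'
#' Rank-normalises the draws, splits each chain in half, and estimates the
#' effective sample size from the multi-chain autocorrelation sequence using
#' Geyer's initial monotone positive sequence truncation. This measures the
#' resolution of the bulk of the posterior (means, medians, central
#' intervals).
#'
#' @param draws Numeric matrix, iterations x chains.
#' @return A single numeric ESS value (`NA` for degenerate constant input).
#' @export
bulk_ess <- function(draws) {
  draws <- as.matrix(draws)
  check_chain_shape(draws)
  if (max(draws) == min(draws)) {
    warning("constant draws; ESS undefined")
    return(NA_real_)
  }
  z <- rank_normalize(draws)
  ess_from_chains(split_chains(z))
}

check_chain_shape <- function(draws) {
  if (ncol(draws) < 2L) stop("need >= 2 chains", call. = FALSE)
  if (nrow(draws) < 4L) stop("need >= 4 iterations per chain", call. = FALSE)
  invisible(draws)
}

split_chains <- function(draws) {
  n <- nrow(draws) %/% 2L
  cbind(draws[seq_len(n), , drop = FALSE],
        draws[nrow(draws) - n + seq_len(n), , drop = FALSE])
}

rank_normalize <- function(draws) {
  s <- length(draws)
  z <- qnorm((rank(draws, ties.method = "average") - 3 / 8) / (s + 1 / 4))
  matrix(z, nrow = nrow(draws), ncol = ncol(draws))
}

# Stan-style multi-chain ESS on an iterations x chains matrix
ess_from_chains <- function(chains) {
  n <- nrow(chains); m <- ncol(chains)
  acov <- apply(chains, 2, function(x) {
    acf(x, lag.max = n - 1L, type = "covariance", plot = FALSE,
        demean = TRUE)$acf[, 1, 1]
  })
  chain_var <- acov[1, ] * n / (n - 1)
  w <- mean(chain_var)
  mean_var <- w * (n - 1) / n
  var_plus <- mean_var + if (m > 1) var(colMeans(chains)) else 0
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (w - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  max_pairs <- (n - 1) %/% 2L
  tau <- 0
  prev <- Inf
  for (k in 0:max_pairs) {
    i <- 2 * k + 1
    if (i + 1 > length(rho)) break
    pair <- rho[i] + rho[i + 1]
    if (k > 0 && pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + pair
  }
  tau <- max(2 * tau - 1, 1 / log10(n * m))
  n * m / tau
}

#' Per-parameter convergence diagnostics for a fit
#'
#' @param fit A `drought_fit`.
#' @return Tibble with `term`, `rhat`, `ess` and pass flags against the
#'   pipeline gates (Rhat <= 1.01, bulk ESS >= 400).
#' @export
compute_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "drought_fit"))
  terms <- dimnames(fit$draws)[[3]]
  purrr::map_dfr(terms, function(tm) {
    m <- fit$draws[, , tm, drop = TRUE]
    tibble::tibble(term = tm, rhat = split_rhat(m), ess = bulk_ess(m))
  }) |>
    dplyr::mutate(rhat_ok = .data$rhat <= 1.01, ess_ok = .data$ess >= 400)
}

#' Posterior predictive check for the binary outcome
#'
#' For each of `n_replicates` posterior draws, simulates a replicate outcome
#' vector from the fitted likelihood and records its mean. The tail
#' probability is the fraction of replicate means at or above the observed
#' outcome rate; values far from 0.5 (near 0 or 1) flag misfit of the
#' marginal rate. Binned replicate means are returned as density-overlay
#' data.
#'
#' @param fit A `drought_fit`.
#' @param input The `drought_model_input` the model was fitted to.
#' @param n_replicates Number of posterior draws to simulate from.
#' @param seed Integer seed for the replicate simulation.
#' @return A `ppc_result` list: `observed_mean`, `replicate_means`,
#'   `tail_prob` and `density` (tibble of bin midpoints and densities).
#' @export
posterior_predictive <- function(fit, input, n_replicates = 200L, seed = 1L) {
  stopifnot(inherits(fit, "drought_fit"),
            inherits(input, "drought_model_input"))
  terms <- dimnames(fit$draws)[[3]]
  flat <- matrix(fit$draws, ncol = length(terms),
                 dimnames = list(NULL, terms))
  set.seed(seed)
  idx <- sample.int(nrow(flat), n_replicates, replace = n_replicates > nrow(flat))
  coef_cols <- colnames(input$X)
  a_cols <- paste0("a[", input$country_levels, "]")
  rep_means <- vapply(idx, function(i) {
    eta <- flat[i, a_cols][input$country] +
      drop(input$X %*% flat[i, coef_cols])
    mean(rbinom(length(eta), 1L, plogis(eta)))
  }, numeric(1))
  obs <- mean(input$y)
  h <- graphics::hist(rep_means, breaks = 30, plot = FALSE)
  structure(
    list(observed_mean = obs,
         replicate_means = rep_means,
         tail_prob = mean(rep_means >= obs),
         density = tibble::tibble(mid = h$mids, density = h$density)),
    class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("<ppc_result> observed mean %.4f, %d replicates, tail prob %.3f\n",
              x$observed_mean, length(x$replicate_means), x$tail_prob))
  invisible(x)
}
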