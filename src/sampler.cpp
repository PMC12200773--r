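#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(z)) without overflow
static inline double softplus(double z) {
  return z > 0.0 ? z + log1p(std::exp(-z)) : log1p(std::exp(z));
}

// Adaptive Metropolis-within-Gibbs for the varying-intercept logistic model:
//   y_i ~ Bernoulli(inv_logit(a[c_i] + x_i' beta))
//   a_c ~ Normal(mu, sigma^2)
//   beta_j, mu ~ Normal(0, prior_sd^2)
//   sigma ~ Half-Normal(sigma_prior_sd)
// Coefficients and country intercepts move by per-coordinate random-walk MH
// (proposal scales adapted toward 0.44 acceptance during warmup only, in
// batches of 50 with diminishing step, then frozen); mu is a conjugate Gibbs
// draw given the intercepts; sigma moves by MH on the log scale. Uses R's
// RNG, so draws are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix mwg_logistic(const IntegerVector& y,
                           const NumericMatrix& X,
                           const IntegerVector& country,  // 0-based
                           const int n_country,
                           const int n_iter,
                           const int n_warmup,
                           const NumericVector& init,
                           const double prior_sd = 1.0,
                           const double sigma_prior_sd = 1.0,
                           const int thin = 1) {
  const int n = y.size(), p = X.ncol(), C = n_country;
  if (X.nrow() != n || country.size() != n)
    stop("dimension mismatch between y, X and country");
  const int n_par = p + C + 2;
  if (init.size() != n_par) stop("init has wrong length");

  // rows grouped by country for cheap intercept updates
  std::vector<std::vector<int>> rows(C);
  for (int i = 0; i < n; ++i) {
    int c = country[i];
    if (c < 0 || c >= C) stop("country index out of range");
    rows[c].push_back(i);
  }

  NumericVector beta(p), a(C);
  for (int j = 0; j < p; ++j) beta[j] = init[j];
  for (int c = 0; c < C; ++c) a[c] = init[p + c];
  double mu = init[p + C];
  double sigma = init[p + C + 1];
  if (sigma <= 0) stop("initial sigma must be positive");

  std::vector<double> eta(n);
  for (int i = 0; i < n; ++i) {
    double e = a[country[i]];
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
  }

  // proposal log-scales: p coefficients, C intercepts, 1 for log-sigma
  std::vector<double> step(p + C + 1, 0.1);
  std::vector<int> acc(p + C + 1, 0), prop(p + C + 1, 0);
  const int batch = 50;
  const int sigma_reps = 4;  // sigma updates are O(C): repeat for mixing

  const int n_keep = (n_iter - n_warmup) / thin;
  NumericMatrix out(n_keep, n_par);
  int kept = 0, nbatch = 0;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    // --- coefficients ---
    for (int j = 0; j < p; ++j) {
      double d = step[j] * norm_rand();
      double dll = -(beta[j] + d) * (beta[j] + d) / (2 * prior_sd * prior_sd)
                   + beta[j] * beta[j] / (2 * prior_sd * prior_sd);
      for (int i = 0; i < n; ++i) {
        double x = X(i, j);
        if (x == 0.0) continue;
        double de = d * x;
        dll += y[i] * de - softplus(eta[i] + de) + softplus(eta[i]);
      }
      prop[j]++;
      if (log(unif_rand()) < dll) {
        for (int i = 0; i < n; ++i) {
          double x = X(i, j);
          if (x != 0.0) eta[i] += d * x;
        }
        beta[j] += d;
        acc[j]++;
      }
    }
    // --- country intercepts ---
    for (int c = 0; c < C; ++c) {
      double d = step[p + c] * norm_rand();
      double anew = a[c] + d;
      double dll = -(anew - mu) * (anew - mu) / (2 * sigma * sigma)
                   + (a[c] - mu) * (a[c] - mu) / (2 * sigma * sigma);
      for (int i : rows[c]) {
        dll += y[i] * d - softplus(eta[i] + d) + softplus(eta[i]);
      }
      prop[p + c]++;
      if (log(unif_rand()) < dll) {
        for (int i : rows[c]) eta[i] += d;
        a[c] = anew;
        acc[p + c]++;
      }
    }
    // --- mu | a, sigma: conjugate normal ---
    {
      double prec = C / (sigma * sigma) + 1.0 / (prior_sd * prior_sd);
      double s = 0.0;
      for (int c = 0; c < C; ++c) s += a[c];
      double mean = (s / (sigma * sigma)) / prec;
      mu = mean + norm_rand() / std::sqrt(prec);
    }
    // --- sigma: MH on log scale ---
    for (int r = 0; r < sigma_reps; ++r) {
      double t = std::log(sigma);
      double tnew = t + step[p + C] * norm_rand();
      double snew = std::exp(tnew);
      double ss = 0.0;
      for (int c = 0; c < C; ++c) ss += (a[c] - mu) * (a[c] - mu);
      double lp_new = -snew * snew / (2 * sigma_prior_sd * sigma_prior_sd)
                      - C * tnew - ss / (2 * snew * snew) + tnew;
      double lp_old = -sigma * sigma / (2 * sigma_prior_sd * sigma_prior_sd)
                      - C * t - ss / (2 * sigma * sigma) + t;
      prop[p + C]++;
      if (log(unif_rand()) < lp_new - lp_old) {
        sigma = snew;
        acc[p + C]++;
      }
    }
    // --- warmup-only diminishing adaptation ---
    if (it < n_warmup && (it + 1) % batch == 0) {
      ++nbatch;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)nbatch));
      for (size_t k = 0; k < step.size(); ++k) {
        double rate = prop[k] > 0 ? acc[k] / (double)prop[k] : 0.0;
        step[k] *= std::exp(rate > 0.44 ? delta : -delta);
        acc[k] = 0;
        prop[k] = 0;
      }
    }
    if (it >= n_warmup && (it - n_warmup) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < p; ++j) out(kept, j) = beta[j];
      for (int c = 0; c < C; ++c) out(kept, p + c) = a[c];
      out(kept, p + C) = mu;
      out(kept, p + C + 1) = sigma;
      ++kept;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
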