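# droughtlink

Linking gridded drought exposure to survey outcomes.

`droughtlink` is for epidemiologists and climate-health researchers who
need to connect a gridded drought index to georeferenced survey
microdata and estimate exposure-outcome associations. It implements,
as a tested R pipeline:

1. **Drought characterisation** from monthly SPEI (Standardized
   Precipitation-Evapotranspiration Index) series. A month is *dry* when
   SPEI ≤ −1. Maximal dry runs define droughts by duration (*count
   method*: runs of ≥ 5 consecutive dry months) and by intensity (*sum
   method*: runs whose summed SPEI ≤ −17.5), plus the months and cycles
   meeting both. A *standardised dryness intensity* summarises a window:

   sdi = (Σ cycle sums) / (total sum-method drought months / number of sum-method cycles)

   Four exposure categories are assigned over the 48 months before each
   respondent's interview: *slight to moderate* (any month with
   −1 < SPEI < 0), *very dry* (sample top 10% by sdi), *recent and long*
   (> 12 consecutive dry months within the trailing 24), and *prolonged
   and extreme* (sample top 10% of months meeting both methods).
2. **Spatial linkage**: cell-level measures are coverage-weight-averaged
   to census districts and joined to respondents by district and
   interview month.
3. **Association modelling**: for each category, a varying-intercept
   Bayesian logistic regression

   logit P(yᵢ = 1) = a_c[i] + β·xᵢ + γ′zᵢ,  a_c ~ N(μ, σ²),

   with N(0, 1) priors on coefficients and μ and Half-Normal(1) on σ,
   sampled by an adaptive Metropolis-within-Gibbs scheme (Rcpp), with
   split-R̂ / bulk-ESS convergence gates, posterior predictive checks,
   and survey-weighted prevalence tables.
4. **Synthetic data**: a generator producing SPEI-like grids with
   injected drought episodes and a multi-country cohort drawn from the
   model with known coefficients — the ground truth behind every test.

Everything is tidyverse-shaped: functions take data frames first and
return tibbles, fitted models have `tidy()`/`glance()`/`autoplot()`
methods, and the pipeline reads and writes plain CSV/JSON.

## Worked example

Summarise one 48-month window containing a single 7-month drought at
depth −2.8 (sum −19.6, so it qualifies under both methods):

```r
library(droughtlink)
spei <- c(rep(0.4, 20), rep(-2.8, 7), rep(0.2, 21))
summarize_window(spei, pipeline_config())
#> # A tibble: 1 × 10
#>   n_dry n_count n_sum n_both cycles_count cycles_sum cycles_both   sdi
#>   <int>   <int> <int>  <int>        <int>      <int>       <int> <dbl>
#> 1     7       7     7      7            1          1           1  -2.8
```

All 7 dry months qualify under both the count method (run ≥ 5) and the
sum method (−19.6 ≤ −17.5), forming one drought cycle per method; the
standardised dryness intensity is −19.6 / (7/1) = −2.8.

Run the whole pipeline on a synthetic study (14 countries, 5,000
respondents, one model per exposure category):

```r
res <- run_pipeline(pipeline_config(seed = 1), "out")
res$report$association
#> # A tibble: 4 × 6
#>   exposure           estimate    se    or ci_low ci_high
#>   <chr>                 <dbl> <dbl> <dbl>  <dbl>   <dbl>
#> 1 slight_to_moderate   0.0318 0.136 1.03   0.794    1.35
#> 2 very_dry            -0.0726 0.193 0.930  0.626    1.33
#> 3 recent_and_long     -0.163  0.112 0.849  0.680    1.05
#> 4 prolonged_extreme    0.0701 0.129 1.07   0.829    1.39
glance(res$fits$prolonged_extreme)
#> # A tibble: 1 × 9
#>   category           n n_dropped n_countries chains total_draws max_rhat min_ess
#> 1 prolonged_ext…  4992         8          14      4        6000     1.01    427.
```

Each row is one fit: the posterior-mean log-odds coefficient of that
exposure category (everyone else as reference), its posterior SD, the
odds ratio `exp(estimate)`, and the 95% credible interval on the OR
scale. The `glance()` row shows the complete-case sample size, the
dropped-row count, and the worst convergence diagnostics across
reported parameters (gates: R̂ ≤ 1.01, bulk ESS ≥ 400). At n ≈ 5,000
the intervals are wide; the simulated effects (−0.156 … 0.197) are
recovered tightly in the n = 20,000 recovery study the acceptance
script runs.

A thin command-line wrapper with `simulate` / `exposure` / `link` /
`fit` / `report` subcommands lives at `inst/cli/droughtlink.R`.

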