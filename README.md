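# heighttrends

Estimation of mean adult height at age 18 by country, sex and birth
cohort (1896–1996) from pooled population-based survey summaries, with a
hierarchical Bayesian model, a blocked Gibbs MCMC sampler, a synthetic
survey-database generator, and a stratified country-holdout validation
protocol.

## The problem

Height in early adulthood integrates childhood and adolescent nutrition,
infection and living conditions, and predicts longevity, disease risk and
earnings. Reconstructing a century of cohort trends for every country
requires pooling surveys that differ in year, age coverage, and sampling
frame — and that report only summary statistics (mean measured height,
SE, n) by sex and standard age group (18, 19, 20–29, then ten-year
groups to 80+). This package is for biostatisticians and epidemiologists
who need that reconstruction machinery end to end: data-preparation
rules, model, sampler, diagnostics, validation and reporting, all
exercisable on synthetic data because the real pooled database is not
public at record level.

## The model

Observed study means are noisy readings of a country's cohort curve.
For observation \(i\) (study × sex × age-group cell):

```
y_i ~ N( mu_c(t_i) + gamma * (age_i - 18) + b_j(i) ,  se_i^2 + omega^2 + nu^2_l(i) )

mu_c(t) = [alpha_0 + alpha_g + alpha_r + alpha_c]
        + [beta_0 + beta_g + beta_r + beta_c] * (t - 1946)
        + u_0(t) + u_g(t) + u_r(t) + u_c(t)
```

with birth cohort `t_i = survey year − mid-age of the age group`.
Intercept and slope deviations are hierarchically shrunk
(country → region → super-region → world); the non-linear components
`u(.)` are second-order random walks (curvature penalised, linear trends
free) under exact sum-zero and zero-linear-moment constraints; `gamma`
is the linear age-drift slope; subnational and community sources carry a
random offset `b_j ~ N(0, tau^2_l)` and extra residual variance
`nu^2_l`. Fits are sex-stratified throughout. Inference is blocked Gibbs
(exact multivariate-normal updates for all effect blocks, conjugate
inverse-gamma updates for most variances, log-scale Metropolis for the
residual variances), with Brooks–Gelman–Rubin diagnostics and
2.5th–97.5th percentile credible intervals. See the methods vignette
(`vignettes/height-model.Rmd`) for the full account.

## Worked example

```r
library(heighttrends)

world <- simulate_world(n_countries = 12, n_regions = 4, n_super_regions = 2,
                        design = survey_design(studies_per_country = c(min = 3, max = 8)),
                        seed = 42)
analysis <- filter_analysis_set(world$observations)
fit_m <- fit(analysis$retained[analysis$retained$sex == "male", ],
             world$hierarchy, model_config(grid_step = 2),
             mcmc_config(n_chains = 2, n_burnin = 500, n_samples = 1500, seed = 7))
check_convergence(fit_m)$converged         # TRUE (max PSRF 1.058)
summarize_fit(fit_m, countries = "C001", cohorts = c(1896, 1946, 1996))
#> # A tibble: 3 × 6
#>   country sex   birth_cohort mean_cm lo_cm hi_cm
#> 1 C001    male          1896    155.  150.  161.
#> 2 C001    male          1946    161.  161.  162.
#> 3 C001    male          1996    164.  160.  167.
century_change(fit_m, countries = "C001")
#>   country sex    from    to change_cm lo_cm hi_cm
#> 1 C001    male   1896  1996      8.05  1.44  14.5
```

The generative truth for C001 at those cohorts is 155.0, 161.5 and
163.7 cm: the posterior means track it within a few tenths of a
centimetre where data are dense (mid-century) and the intervals widen
toward the data-sparse 1896 and 1996 edges, which is exactly the
behaviour the hierarchical model should show. `century_change()`
computes the 1896→1996 gain on the posterior sample of the difference,
draw by draw.

## Analysis workflow

The `analysis/` scripts run the full study pipeline on a 60-country
synthetic world and write tables under `results/`:

1. `01_simulate.R` — synthetic world; analysis-set filter, exclusion
   log, duplicate flags, data-availability strata.
2. `02_fit.R` — sex-stratified fits, convergence report,
   `estimates.csv`, `diagnostics.json` (on this world: max PSRF ≤ 1.03;
   mean absolute error against generative truth 0.32 cm with 95.2% of
   true values inside the 95% intervals).
3. `03_validate.R` — stratified 10% country holdout, five repetitions
   (global interval coverage 96–97% on this world).
4. `04_report.R` — century changes, rankings, sex gaps, trend figures.

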