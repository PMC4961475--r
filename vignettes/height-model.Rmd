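---
title: "Estimating a century of adult height trends from pooled survey summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating a century of adult height trends from pooled survey summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

National statistics on adult height come from heterogeneous
population-based surveys: different countries, years, age ranges, and
sampling frames, each reporting only summary statistics (mean measured
height, standard error, sample size) by sex and standard age group. The
goal is a coherent reconstruction of mean height **at age 18 by birth
cohort** — here 1896 to 1996 — for every country, including countries and
periods with little or no data, with honest uncertainty.

Two features of the data drive the design:

* A survey measures many birth cohorts at once: a study in year $y$
  reporting the 20–29 age group is informing the cohort born around
  $y - 24.5$. Birth cohort is reconstructed as survey year minus the
  mid-age of the age group, so cohorts are often half-integers.
* Only about half of the sources are nationally representative; the rest
  cover subnational regions or single communities and may be shifted
  relative to the national mean, with extra noise on top of sampling
  error.

## The model

All analyses are stratified by sex. For observation $i$ (one study ×
age-group cell with observed mean $y_i$, sampling variance $s_i^2$),

$$
y_i \sim \mathcal N\!\big(\mu_{c(i)}(t_i) + \gamma\,(a_i - 18) + b_{j(i)},\;
s_i^2 + \omega^2 + \nu^2_{\ell(i)}\big),
$$

where $t_i$ is the birth cohort, $a_i$ the mid-age at measurement,
$\ell(i)$ the coverage level, and the population curve for country $c$ is

$$
\mu_c(t) = \underbrace{\alpha_0 + \alpha_{g(c)} + \alpha_{r(c)} + \alpha_c}_{\text{intercepts}}
 + \underbrace{(\beta_0 + \beta_{g(c)} + \beta_{r(c)} + \beta_c)}_{\text{slopes}} (t - t_0)
 + \underbrace{u_0(t) + u_{g(c)}(t) + u_{r(c)}(t) + u_c(t)}_{\text{non-linear components}} .
$$

* **Hierarchy.** Countries nest in regions, regions in super-regions,
  super-regions in the world. Intercept and slope deviations at each
  level are zero-mean normal with level-specific variances, so countries
  with sparse data shrink toward their region's trend ("borrowing
  strength") while data-rich countries follow their own data.
* **Non-linear trends.** Each $u(\cdot)$ is a second-order random walk
  (RW2) on the cohort grid: second differences are independent normals,
  so curvature is penalised and linear trends are free. Because explicit
  intercept and slope terms are present, each RW2 vector carries two
  exact identifiability constraints — zero sum and zero linear moment —
  making the decomposition into line + curvature unique. One RW2
  innovation variance is shared by all units within a level.
* **Age drift.** A cohort's measured mean changes as it ages (height
  loss plus survival effects). A single linear slope $\gamma$ per sex
  absorbs this; empirically the association is close to linear
  (roughly −0.2 cm per decade for men, −0.3 for women), and the linear
  form is cheap to fit.
* **Study-type components.** Subnational and community studies get a
  random offset $b_j \sim \mathcal N(0, \tau^2_\ell)$ (systematic
  difference from the national mean) and an extra residual variance
  $\nu^2_\ell$; national studies get neither, and a small global
  residual $\omega^2$ covers non-sampling noise common to all sources.

Priors: diffuse normals on $\alpha_0, \beta_0, \gamma$; inverse-gamma
(shape 2, weakly informative scales set in `model_config()`) on every
variance, chosen for conjugacy. Half-integer cohorts evaluate the RW2
components by linear interpolation between grid points; integer cohorts
hit the grid exactly.

## Inference

The model is conditionally Gaussian given variances, so the sampler is a
blocked Gibbs scheme (implemented in C++):

1. **Effect blocks.** The world block $(\alpha_0, \beta_0, \gamma, u_0)$
   and each super-region, region and country block
   $(\alpha_\cdot, \beta_\cdot, u_\cdot)$ are drawn from their exact
   multivariate-normal full conditionals. The RW2 constraints are imposed
   exactly by conditioning-by-kriging: sample from the unconstrained
   conditional (with the constraint directions regularised, which does
   not change the density on the constraint subspace) and subtract the
   conditional projection onto the violated constraints.
2. **Translation sweeps.** A balanced shift — add $\delta$ to a parent
   level and subtract it from all its children — leaves every fitted mean
   unchanged, so these directions are identified only by the prior and
   mix slowly under per-unit updates. An extra Gibbs step samples each
   such shift (scalar for intercepts and slopes, a constrained vector for
   RW2 components) from its Gaussian full conditional. This took the
   worst potential-scale-reduction factors on small test fits from ≈3.9
   to below 1.06 at no measurable cost.
3. **Variances.** Deviation variances, RW2 innovation variances and
   study-offset variances have conjugate inverse-gamma updates. The
   residual variances $\omega^2, \nu^2$ sit inside $s_i^2 + \cdots$ and
   are not conjugate; they use log-scale random-walk Metropolis (step
   0.5, acceptance typically 30–60%).
4. **Study offsets** are scalar conjugate draws.

Chains start from dispersed points: effects at zero (world intercept at
the precision-weighted data mean), variances at prior medians scaled by
0.25, 1, 4, 16 per chain. Defaults are 4 chains, 2000 burn-in, 5000
retained draws; convergence is monitored with Brooks–Gelman–Rubin PSRFs
(flag threshold 1.1) on country heights at selected cohorts, $\gamma$,
and all variances, plus trace data. Reported intervals are the
2.5th–97.5th posterior percentiles; all quantiles use linear
interpolation between order statistics (R type 7). Every source of
randomness descends from one integer seed; identical seeds give
bit-identical draw streams.

## The synthetic world

The real pooled database is not public at record level, so the package
generates worlds with the statistical structure the model assumes,
making estimation and validation testable end to end:

* **Hierarchy** of 60 countries / 12 regions / 4 super-regions by
  default, balanced at random.
* **Truth surfaces** per sex: world line anchored at the 1896 cohort
  (163 cm men / 152 cm women, gaining 0.10 / 0.09 cm per cohort year),
  normal intercept deviations with SDs 4 / 2.5 / 1.5 cm (super-region /
  region / country) giving a cross-country range near 20 cm, slope
  deviation SDs 0.03 / 0.02 / 0.025 cm/yr giving century gains spanning
  roughly 0–20 cm, and constrained RW2 components (innovation SDs
  0.010–0.015 cm) producing the few-centimetre plateau and acceleration
  features seen in real cohort curves. Age drift −0.02 / −0.03 cm per
  year of age.
* **Survey database**: study counts per country from 3–30 with
  probability ∝ 1/k — real pooled databases average under ten sources
  per country with a long survey-poor tail, and this skew is what
  populates all three data-availability strata (data-rich / average /
  data-poor) for both sexes; coverage levels drawn at the real 54/14/32
  national/subnational/community mix; survey years uniform on
  1960–2014; each study reports either the full standard age-group set
  or a short contiguous run (1–4 groups), as conscript boards or working-
  age surveys do; per-cell sample sizes log-normal (median 400, clamped
  to 25–5000) with SE = 7 cm / √n from a within-group SD of 7 cm (a
  typical adult height SD); subnational and community studies draw
  offsets with SD 1.0 / 1.5 cm and extra residual SD 0.5 / 1.0 cm —
  placeholder magnitudes for sensitivity work, as no published values
  exist.

What the generator does **not** emulate: temporal clustering of surveys,
non-response and protocol drift, migration, within-study correlation of
age-group cells beyond the shared study offset, and any real-country
geography. Passing tests therefore show the method is correct and
calibrated *when its assumptions hold*, not that real-world estimates
carry these error magnitudes.

## Validation protocol

`make_holdout_plan()` withholds ~10% of countries with data per
repetition (at least one per stratum), stratified by the
data-availability classes and sex, five repetitions by default.
`run_holdout()` refits on the remaining countries — the withheld
countries stay in the hierarchy with no data, exactly like a country
never surveyed — and predicts every held-out observation at its actual
cohort and age. Errors are estimate − held-out *observed* mean (a
truth-based mode exists for simulation studies); coverage uses
observation-level predictive intervals, which add the study-offset and
residual variances to the population-curve draws, since the quantities
being predicted are observed study means. Values on an interval bound
count as covered.

On synthetic worlds the coverage criterion behaves as theory says it
should: subset coverage sits near the nominal 95% and comfortably above
the 90% floor reported for the real analysis. The median-error and
median-absolute-error ceilings printed for the real analysis (±0.2 cm
and 1.0 cm per subset) are **not** reproducible at desk scale, for a
structural reason worth stating precisely: a stratum × sex × repetition
cell here holds only one to four held-out countries, so the cell median
is dominated by a single country's region-level prediction error, whose
SD under any realistic cross-country spread is 1.5–2.5 cm. Meeting
±0.2 cm per cell would require within-region country SDs below ~0.1 cm.
The real analysis pools far more countries per cell (and its regions,
grouped by geography and income, are empirically more homogeneous than a
random synthetic assignment). The acceptance suite asserts the
full-scale bounds as published and the error criteria fail honestly at
this scale; the coverage criterion passes.

## Numerical choices and edge cases

* Cohort grid 1896–1996; analyses here subsample to 2-year steps (51
  points) for speed, with half-integer cohorts interpolated; the grid is
  centred at $t_0 = 1946$ for conditioning.
* "80+" mid-age is fixed at 85 (symmetric 80–90 convention; configurable),
  so e.g. a 1960 survey of the 80+ group informs the 1875 cohort — which
  the analysis filter then drops as pre-1896.
* Ten-year groups are closed integer ranges with midpoint (lo+hi)/2,
  giving the half-integer cohorts the subtraction rule implies.
* Duplicate flagging (same country and year) is advisory only; the
  real workflow resolves duplicates by human review.
* Ranking ties break alphabetically by country code; rankings and sex
  gaps are computed on posterior means, while *changes over time* are
  computed on the posterior sample of the difference, draw by draw — the
  interval of a difference is much narrower than differencing interval
  endpoints when the two ends are correlated.
* Degenerate inputs: empty observation sets are rejected; a single
  country works (it simply shrinks to the world line); a single chain
  can be fitted but convergence checking demands at least two.
* Problem sizes used in the shipped analyses and tests: 60-country
  worlds with 2-year grids and 2 chains × 1500 retained draws for the
  full and holdout fits; 12-country worlds with 4-year grids for
  replicate studies; the exactness oracle runs on a 2-country,
  grid-length-5 instance where the full posterior is computable densely.

## Open choices made here

The published description of the real analysis defers its equations to a
methods companion, so this package fixes the unstated pieces and flags
them for sensitivity analysis: normal hierarchical deviations with
inverse-gamma hyperpriors; one RW2 precision per level shared across
units (not one per country); $\nu^2 \equiv 0$ for national sources with
a small global $\omega^2$; urban/rural scope carried as metadata only;
the age-group set taken literally (18 and 19 never merged). Survivorship
is not modelled beyond the linear age term. Spatial correlation between
neighbouring countries and covariates (GDP, urbanisation) are out of
scope.

## Known limitations

* The sampler's cost per iteration is linear in observations and units
  but the dense per-unit solves scale cubically in grid length; very
  fine grids (yearly, 101 points) with many countries are noticeably
  slower than the 2-year default used here.
* Inverse-gamma hyperpriors are informative near zero; with very few
  units per level (e.g. 4 super-regions) level variances are largely
  prior-driven, which is inherent to such shallow hierarchies.
* Holdout error metrics at this scale have high Monte-Carlo variance
  across worlds and seeds (few countries per cell), as discussed above.
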