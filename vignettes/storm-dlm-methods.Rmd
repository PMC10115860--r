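---
title: "Methods: matched distributed-lag models for storm-period hospitalization risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched distributed-lag models for storm-period hospitalization risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stormlag)
```

## The model

The estimand is the relative risk of cause-specific hospitalization on each
day of the 10-day period surrounding a tropical cyclone's closest approach
to a ZCTA (lags −2 through +7), compared with seasonally matched unexposed
days. On the matched day-level table, `stormlag()` fits the mixed-effects
Poisson regression

$$\log E[Y_{zt}] = \alpha + \alpha_z + \sum_{l=-2}^{7}\beta_l\,x_{t+l,z}
  + \log n_{zy} + \boldsymbol\delta'\mathrm{DOW}_t +
  \boldsymbol\gamma'\mathrm{Year}_t,$$

with $Y_{zt}$ the daily count in ZCTA $z$, $\alpha_z \sim N(0,\sigma^2)$ a
ZCTA random intercept, $x_{t+l,z}$ the indicator that day $t$ lies at lag
$l$ of a storm day, and $\log n_{zy}$ an offset for the ZCTA-year
beneficiary denominator so the mean is a rate. Day-of-week enters as
categorical indicators with Monday as reference; calendar year as
categorical indicators with the earliest year present as reference.

Lag-specific relative risks are $RR_l = e^{\beta_l}$ with Wald intervals
$e^{\beta_l \pm z_{1-\alpha/2}\,se_l}$. The cumulative 10-day relative risk
is $e^{\sum_l \beta_l}$; its standard error is
$\sqrt{\mathbf 1'\,V\,\mathbf 1}$ over the joint covariance $V$ of the lag
coefficients (delta method on the summed coefficients — the standard
construction for a summed-lag contrast). By construction the cumulative RR
equals the product of the lag RRs exactly.

### Assumptions

* Counts are conditionally Poisson given the linear predictor; no
  overdispersion correction is applied by default (a quasi-Poisson scale is
  available on the fixed-effect route via `quasi = TRUE`).
* Exposure is binary at the ZCTA-day level: a day either is or is not at
  lag $l$ of a ≥ 21 m/s storm. Wind intensity beyond the threshold does not
  enter the risk model (it is summarized separately per ZCTA).
* Strata in effect-modification contrasts are fitted independently and
  compared with a two-sample z test on log RRs,
  $z = (\log RR_a - \log RR_b)/\sqrt{se_a^2 + se_b^2}$. Community strata
  partition ZCTAs, so approximate independence holds; individual strata
  share calendar windows but concern disjoint beneficiaries.

## The matched design

Each storm-ZCTA exposed day is matched to `k = 10` control index days that
must

1. fall in a *different* calendar year within the study period,
2. lie within ±7 days of the exposed day's day-of-year,
3. not lie within 3 days (inclusive) of any storm day in that ZCTA, and
4. carry a complete −2..+7 window inside the study period.

Sampling is uniform without replacement from the eligible set; if fewer
than 10 candidates exist all are used and the deficit is logged (a
`require_full` switch drops deficient sets instead). An exposed day whose
own window leaves the study period is ineligible, which keeps every
retained set balanced at 11 windows × 10 days = 110 rows.

Numerical conventions chosen where the design is silent, all deterministic
and covered by tests:

* **Leap days.** Day-of-year distance is month-day distance on a 365-day
  circle with February 29 mapped to February 28, avoiding integer
  day-of-year drift across leap years.
* **The 3-day exclusion** is inclusive (|d − storm| ≤ 3 excluded) and
  applies to the control *index* day only, not its whole window; control
  windows may therefore overlap each other or incidentally contain another
  storm's lagged days. Anything stronger would impose structure the design
  does not state.
* **Ties in county overlap** (exposure downscaling) break to the
  lexicographically smallest county identifier, with a warning.
* **Ties at a community median** label "below"; "above" is strict.
* One exposed day per storm-ZCTA: the closest-approach date.

## Estimation and numerical choices

The random intercept is estimated by Laplace-approximated maximum
likelihood (`lme4::glmer`, one adaptive quadrature point), using the
`nloptwrap` BOBYQA optimizer, which on tables of ~40k rows converges in a
fraction of the time of the two-stage default with coefficient agreement to
about 1e−3 against the fixed-effect route. The GLM route (`random_intercept
= "never"`, or the automatic fallback when the mixed optimizer fails) uses
ZCTA indicator fixed effects, IRLS tolerance 1e−8, and a 200-iteration cap;
the fit record stores the method used, the fallback flag, convergence
status, iteration count, and any optimizer messages. With the intercept
variance estimated at ~0 the two routes agree to a few 1e−3 in the lag
coefficients (tested).

A lag indicator whose active rows carry only zero counts is *separated*:
its coefficient diverges to −∞. Such lags are flagged, reported with an
infinite standard error, and poison the cumulative estimate (returned
flagged-unavailable rather than silently wrong).

One diagnostic deliberately not implemented: a per-iteration monotone
likelihood-ascent trace. Neither `stats::glm` nor `lme4::glmer` exposes its
iteration path without refitting under trace hooks; the fit record instead
carries the optimizers' own convergence diagnostics.

## The synthetic-data generator

`simulate_tc_data()` is the forward model of the fitted equation: counts
are drawn Poisson from exactly the linear predictor above with known
parameters, so downstream estimates can be checked against truth. What it
emulates, and the defaults (all configurable via `tc_scenario()`):

* **Storm calendar** — per ZCTA, Poisson(`storms_per_year` × years) storms
  with dates uniform over a June–November season (Atlantic-season realism;
  the season window is configurable) and truncated-normal windspeeds
  (location 27.65 m/s, scale 5, truncated at the 21 m/s threshold). The
  default rate 0.2261/year reproduces a mean burden of ~4.07 storms per
  ZCTA over 18 years, the burden observed for Florida ZCTAs over
  1999–2016. Only qualifying storms are emitted; sub-threshold storms are
  exercised through the exposure module's own tests.
* **Denominators** — beneficiaries per ZCTA-year, uniform in
  [500, 3000] per ZCTA with mild (±3%) year-to-year perturbation. Annual
  granularity is the natural Medicare enrollment resolution; a
  constant-denominator option exists because the enrollment offset need not
  be time-resolved. Subgroup denominators (age 65–74/75–84/85+, sex, dual
  eligibility) are fixed enrollment proportions of the total, with the last
  cell absorbing rounding so subgroup counts sum to ZCTA totals exactly.
* **Community covariates** — ten census-like variables drawn from a
  multivariate normal with a one-factor socioeconomic correlation structure
  by default (any positive-definite correlation can be supplied), rescaled
  to realistic census locations and spreads; percentages are clamped to
  [0, 100].
* **Baseline rate** — `log(8.3e-5)` per beneficiary-day, matching a
  respiratory-disease-like burden (~0.145 admissions per ZCTA-day at the
  mean denominator). The default lag profile sums to 1.47, a cumulative RR
  of ~4.35 with a depressed storm-day effect — the shape seen for
  respiratory admissions. Day-of-week effects include a weekend dip; year
  effects drift 1% per year.
* **Effect modification** — an optional per-lag multiplier on the true lag
  coefficients in ZCTAs above the median of a chosen covariate, so
  stratified recovery can be tested against a known between-strata ratio.

What it does **not** emulate: spatially correlated wind fields (storms are
independent across ZCTAs), evacuation or infrastructure-failure dynamics,
claims-coding artifacts, population displacement after storms, or temporal
drift in community covariates. Passing tests on synthetic data therefore
validate the estimator and design logic, not robustness to those
real-world features.

## Packaged validation scenarios

Three scenarios (`tc_example_scenario()`) back the package's validation
suite and `scripts/acceptance.R`; their sizes are chosen as the smallest
designs that preserve the study's structure while keeping hundreds of
replicates practical on one core:

* **recovery** — the full study geometry (100 ZCTAs, 18 years, ~4 storms
  per ZCTA, random-intercept SD 0.25). A single seeded fit recovers every
  true lag coefficient within 3 standard errors and covers the true
  cumulative RR.
* **null** — all lag effects zero, 12 ZCTAs over the same 18-year
  calendar, no random intercept (so the exact fixed-effect route is used
  per replicate). Over 500 replicates the 95% cumulative-RR interval
  achieves empirical coverage of about 0.91–0.93 depending on the seed,
  and p values of a null between-strata contrast are uniform. The calendar
  length matters here: on a shortened calendar the 10 control windows reuse
  the same days heavily and the duplicated rows understate the variance — a
  property of the matched design worth remembering when applying it to
  short study periods; the slight undercoverage that remains even at 18
  years has the same origin (the same day's count appearing in overlapping
  windows is treated as independent by the likelihood).
* **modifier** — lag-0 log RR of ln 2, doubled in above-median-poverty
  ZCTAs (between-strata RR ratio exactly 2), 40 ZCTAs × 6 years. Over 200
  replicates the mean estimated ratio is unbiased and the contrast is
  significant at α = 0.05 in well over 80% of replicates.

## Known limitations

* Wald intervals throughout; no profile-likelihood or bootstrap intervals.
* The model treats matched rows as independent given covariates; calendar
  days reused across overlapping control windows induce mild dependence
  (see the calibration note above).
* Exposure downscaling assigns each ZCTA its dominant county's storms
  wholesale; an area-weighted windspeed average is a defensible alternative
  the package deliberately does not implement, since assignment-by-largest
  overlap is the documented procedure for this design.
* No multiple-testing adjustment is applied across the ten community
  stratifiers in pipeline output; a Bonferroni column is trivial to add
  downstream and the unadjusted presentation mirrors standard practice for
  these designs.
* Race is carried as a label in synthetic subgroup data but no
  race-stratified analysis path is provided.
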