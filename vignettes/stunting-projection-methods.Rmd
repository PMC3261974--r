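---
title: "Methods: a process-driven model of child stunting under climate scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a process-driven model of child stunting under climate scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stuntcast)
```

## Why a process-driven model

Child stunting (height-for-age more than 2 SD — moderate — or 3 SD —
severe — below the reference mean, in children under 5) has many causes:
insufficient calories, but also sanitation, maternal education, infection,
health-care access. Scenario data for climate impact work are, however,
essentially limited to projected calorie availability, GDP and population.
A purely statistical regression of stunting on those covariates would fit
the present well but has no reason to hold over a 40-year projection,
because the GDP-stunting relationship is mediated by social and political
conditions that shift over time. stuntcast therefore separates the two
channels by stability:

* **Food causes** (`x`, the prevalence of undernourishment, PoU) are linked
  to stunting through an assumed *physiological* coefficient `beta_k`,
  which can reasonably be treated as time-invariant: adequately nourished,
  optimally cared-for children grow at predictable rates everywhere.
* **Nonfood causes** (`w`, the development score) absorb everything
  socioeconomic; their coefficients are re-estimable and carry standard
  errors into the uncertainty analysis.

The model is bilinear — linear in `x`, `w` and their product:

$$y_k = \alpha_k + \beta_k x + \gamma_k w + \theta_k x w,\qquad
  y_1 = 1 - y_2 - y_3 .$$

The interaction term matters: poor socioeconomic conditions amplify the
effect of a calorie shortfall (diarrhoeal disease wasting the calories that
are available, for instance).

## Estimating beta: a low percentile, not a regression slope

If all stunting in some country-year were food-caused, the ratio `y_k / x`
would equal the physiological coefficient; everywhere else it overstates
it, because the numerator includes nonfood stunting. The estimator is
therefore the *minimum* of the ratio distribution in principle. In
practice the extreme minimum is fragile to data error, so the package uses
the 5th percentile as the central estimate and the 1st and 10th as the
plausible range (`estimate_beta()`, percentile policy configurable).
Percentiles interpolate linearly between order statistics at rank
$h = (n+1)p$ (the exclusive-endpoint convention, `quantile(type = 6)`);
the choice is pinned by an order-statistic oracle in the test suite, and
`percentiles = c(0, 0, 0)` recovers the pure minimum. Beta is estimated on
the *full* panel, before the validation holdout is removed: the estimator
is a deliberate approximation and benefits from every record.

## Stepwise attribution and the nonfood fit

With beta fixed, each training record is decomposed as
`r = beta * x` (food-attributable) and `s = y - r` (nonfood plus
interaction), and `s` is regressed on `(1, w, x w)` by OLS — levels fitted
independently, each with its own beta. Three deliberate approximations,
made for parsimony and auditability rather than statistical elegance:

* the three levels are not fitted jointly under a sum-to-one constraint;
  no/mild stunting is closed as `1 - y2 - y3` afterwards;
* `w` and `x w` are treated as independent regressors although they are
  correlated; the design condition number is reported in the fit
  diagnostics so the collinearity is visible rather than hidden;
* negative residuals `s` (possible where `beta * x` exceeds observed
  stunting) are retained — truncating them would bias the fit.

A rank-deficient design (e.g. a panel whose development score is constant,
as happens when every GDP is past saturation) aborts with a diagnostic
rather than returning unstable estimates.

On the published parameter surface, raising `w` *lowers* moderate stunting
while raising severe stunting once undernourishment is high enough
(`x > gamma_2 / |theta_2| ~ 0.6`): children shift from the moderate to the
severe category as conditions worsen. The negative `theta` values also mean
that relieving either cause helps most when the other is already low — to
reduce stunting one must address food access *and* socioeconomic
conditions.

## The development score

The score `w` maps (GDP per capita, Gini) to [0, 1]: 0 where socioeconomic
conditions no longer contribute to stunting, 1 at the baseline global
worst. Its published definition fixes the endpoints and drivers but not
the functional form between them, so the package declares its own
reconstruction: linear interpolation in log inequality-adjusted income
`a = gdp * (1 - gini)` between the saturation income
`a_opt = 10000 * (1 - 0.38)` and the panel minimum `a_worst`,

$$w = \mathrm{clamp}\!\left(\frac{\ln a_{opt} - \ln a}
  {\ln a_{opt} - \ln a_{worst}},\; 0,\; 1\right).$$

Log income is the standard scale on which income relates to health
outcomes, and this form satisfies every stated property: both endpoints,
monotonicity in each driver, and exact saturation (`w = 0` for any
GDP >= $10,000 with Gini <= 0.38). The form is isolated behind
`development_score()` so an alternative can be swapped in.
`saturation_sensitivity()` re-runs a projection with the saturation
replaced by the best observed adjusted income; on synthetic scenarios the
difference is small, consistent with saturation being a mild assumption.
Gini is held at baseline in all projections — no credible Gini projections
exist.

## Undernourishment

PoU follows the FAO framework: the proportion of the population whose
habitual intake falls below the minimum dietary energy requirement (MDER),
under a lognormal intake distribution with mean equal to the per capita
dietary energy supply (DES) and a country-specific CV:
$\sigma = \sqrt{\ln(cv^2+1)}$, $\mu = \ln(des) - \sigma^2/2$,
$PoU = \Phi\big((\ln mder - \mu)/\sigma\big)$. The parameterization is
mean-preserving by construction (unit-tested to 1e-9) and the CDF is
checked against a 10^6-draw Monte Carlo count. In projections only DES
varies by scenario; CV and MDER stay at baseline, since no projections for
either exist. The distribution family sits behind `intake_distribution()`
and is pluggable; the skew-adjusted FAO refinements are out of scope.

## Monte Carlo projection

Parameter uncertainty propagates by standard Monte Carlo
(`simulate_country()`): `alpha, gamma, theta ~ Normal(point, SE)`;
`beta ~ Uniform(low, high)` over its percentile range. Each draw is
evaluated through the bilinear model and accepted iff `0 < y < 1`; draws
continue, in order, until 100,000 (configurable) estimates are accepted.
Because the model is linear in its parameters, a zero-rejection run has
accepted mean equal to the surface at the parameter means — a property the
tests exploit as an oracle. Rejections are counted separately below 0 and
above 1: one-sided rejection biases the accepted mean (upward when only
sub-zero draws are rejected — typical for severe stunting, whose surface
sits near zero in well-off, well-fed cells), so the proportions rejected
are always part of the output rather than an optional diagnostic. If a
probe batch shows an acceptance rate under 1%, the run aborts: the model
is being evaluated far outside the conditions it was fitted to, and an
"estimate" formed almost entirely by rejection would be meaningless.
Projected PoU above 76% — the maximum undernourishment in the fitting
data — triggers a caution without aborting.

Reproducibility: each (country, scenario, level) gets a sub-seed derived
deterministically from the master seed by string hashing, so countries are
independent, runs are bit-identical per seed, and adding a country does
not perturb the others' streams. Whether draws should instead be shared
across countries within a region is unknowable from the published
description; independent draws were chosen — regional *means* are
unaffected in expectation, only the regional spread differs.

Aggregation is population-weighted (projected under-5 population by
default) and draw-wise, so the regional mean equals the weighted mean of
country means exactly. Relative increases under climate change are
reported unrounded with the rounded value alongside; recomputing published
regional tables from their own rounded cells can disagree with the printed
integer by 1 in such tables, which is why both forms are kept.

## The synthetic-data generator

`generate_panel()` emulates the structure of the real calibration panel —
186 country-year records, 1988-2008, with covariates spanning the observed
ranges (GDP $81-$5,513, Gini 0.17-0.74, PoU 5-70%) — with the published
central parameters as generating truth and Gaussian residuals
(SD 0.02 per level, matching the residual scale of the published fit).
Covariates are drawn independently and uniformly within the ranges;
the ground-truth development anchors sit at the range corners so `w` is a
fixed function of the covariates, not of the realized draw, and the
generator returns them so recovery tests can refit on the generating
scale.

Two safeguards keep the generated proportions valid without corrupting the
error structure: covariate draws are rejected while the noiseless surface
is within 3 residual SDs of a proportion bound (selection on covariates is
ancillary and leaves OLS unbiased), and the rare noise draws beyond 3 SD
that still cross a bound are resampled, not clipped (clipping would place
point masses on the bounds).

`generate_scenarios()` back-solves baseline DES from a target baseline PoU
by root finding (`solve_des()`, checked against the closed form
$\ln des = \ln mder - \sigma\,\Phi^{-1}(PoU) + \sigma^2/2$), then applies
multiplicative calorie effects per scenario — defaults 1.00 (reference),
0.88 and 0.89 for the two climate futures, the order of decline implied by
published scenario PoU shifts — and grows GDP by a per-region factor
(default 5x to mid-century, bracketing published regional projections of
5-9x).

What the generator does **not** emulate: the negative GDP-PoU correlation
of real panels (a Gaussian-copula correlation knob `gdp_pou_cor` exists
but defaults off, for test transparency; note that feasibility screening
alone already induces a mild *positive* association, since low-GDP,
low-PoU draws often imply negative severe stunting and are redrawn),
survey reference-standard heterogeneity, measurement error
in stunting prevalence, and any geographic realism beyond region labels.
Passing tests therefore demonstrate correctness of the estimators and the
pipeline under the model's own assumptions — not that the model is true of
real data; that evidence comes from holdout validation on a real panel.

## Numerical choices and problem sizes

* Holdout size is round-half-up of `fraction * n` (0.2 of 186 gives 37);
  invalid records are dropped with a logged reason, never repaired;
  percent-scaled columns are rescaled only when the *majority* of values
  exceed 1, so a lone out-of-bounds value is treated as the data error it
  is.
* OLS standard errors use the exact `(X'X)^{-1}` factorization; the fit is
  cross-checked against an explicit normal-equations solver to 1e-8 in
  tests.
* Root finding for `solve_des` brackets `[mder/1000, mder*1000]` at
  tolerance 1e-10.
* The test suite runs parameter recovery at 200 replications of n = 149
  panels, Monte Carlo properties at 100,000 accepted draws per level, and
  the PoU oracle at 10^6 draws — sizes chosen so the full suite completes
  in well under a minute while keeping Monte Carlo standard errors far
  below the asserted tolerances.

## Known limitations

Calorie availability is a pure input: the upstream climate-crop-trade
modelling and its (large) uncertainty are not propagated. Stunting enters
only through calories and the development score; micronutrient quality,
food stability and utilization, and direct climate pathways (infection,
heat, water) are absent. The intake distribution and Gini are frozen at
baseline. The three stunting levels are fitted without a joint
constraint, so a projected `y2 + y3 > 1` is possible in principle (it is
reported as a diagnostic, and does not occur under published-scale
parameters). These are properties of the modelling strategy, kept simple
deliberately; the package's job is to make each assumption explicit,
seeded, and testable.
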