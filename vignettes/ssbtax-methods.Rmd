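---
title: "Methods: modelling an SSB tax for Brazil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling an SSB tax for Brazil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbtax)
```

`ssbtax` chains six stages: a synthetic-data generator standing in for the
restricted POF/PNS microdata, demand estimation, caloric-change scenarios,
anthropometric bias correction, a dynamic weight microsimulation, and
outcome/cost accounting. This vignette explains each stage's model and
assumptions, the tunable parameters that matter, the numerical choices,
and what the synthetic data can and cannot tell you about real surveys.

## Why synthetic data

The household purchase file (weekly quantities and expenditures of 57,920
households), the adult 24-h recall file (37,689 adults representing
147.85 million) and the measured anthropometry reference cannot be
redistributed at individual level. The generator therefore emulates their
*structure* with known ground truth:

* log-log demand with income-tertile-specific elasticities of each
  beverage with respect to SSB price (defaults are the published tertile
  estimates, e.g. −1.241/−1.186/−1.126 for SSB itself);
* unit prices with state-level components, so the neighbour-median price
  imputation path is exercised;
* independent Bernoulli zero-purchase thinning per category, with
  probabilities back-derived from the published per-category estimation
  sample sizes (e.g. only 383 of 57,920 households buy light/diet
  beverages);
* right-skewed (log-normal) per-capita income, with tertiles computed at
  weighted cut points; gamma survey weights rescaled exactly to the
  represented totals;
* beverage intake with multiplicative tertile, sex and age-group factors
  reproducing the published group means (national 71.8 kcal/person/day
  from SSB; tertiles 53.5/74.0/86.7; sexes 65.1/79.5; ages
  92.2/62.9/46.9), drawn from a gamma with shape 0.5 so a single recall
  day is strongly right-skewed;
* sex-specific log-normal BMI located so obesity prevalence hits 28.8%
  (women) and 21.2% (men), 25.2% overall, with log-sd 0.18/0.16
  (≈ 4–5 kg/m² SD, typical of adult surveys), heights normal by sex, and
  plausibility truncation (height 1.40–2.10 m, BMI 16–60) mirroring
  standard survey cleaning;
* self-report bias: weight under-reported by an intercept plus a slope in
  true weight, height over-reported by a constant, both larger for women,
  plus reporting noise.

What passing tests on these data *show* is that the estimators and
simulators recover known truths under the study's sampling structure.
What they *cannot* show is robustness to features the generator does not
model: item-level heterogeneity within categories, intra-household
purchase correlation, spatial price gradients beyond a state effect,
usual-intake versus single-day variance, or tertile gradients in BMI.
The demand-noise standard deviation (0.5 on log quantity) and the
intra-category price dispersion are free parameters — the surveys do not
publish them — chosen so that estimation precision at n = 20,000
resembles the published standard errors.

## Demand

Elasticities come from survey-weighted least squares of log quantity on
the log prices of all 11 food/beverage categories, interacted with
income-tertile indicators, plus income and income squared and household
controls, exactly as in the estimating equation; `income_form = "log"`
switches to log income (the verbal description and the equation differ in
the source; the equation as printed is the default). Households with zero
purchases of the *dependent* category are dropped from that regression
(log of zero), which matches the published per-category sample sizes
being far below the full file; their imputed prices still serve as
regressors elsewhere. Missing unit values escalate metro area → state →
national median, requiring at least `min_obs = 5` observed prices per
region ("neighbouring regions" is otherwise undefined).

Cluster-robust standard errors default to clustering on socioeconomic
status as published, but with 3 clusters they are fragile and the fit
warns; simulation work in this package clusters on state (27 clusters).
Parameter recovery is a tested property: at 20,000 households the
embedded tertile elasticities are recovered within 3 standard errors in
at least 95 of 100 seeded replicates.

## Scenarios

Tax effects on consumption are assumed linear in the price change, so
Δkcal = baseline × rate × pass-through × elasticity, per person, with the
tertile's elasticity. Pass-through is fixed at 100% (the source is silent;
full pass-through is the standard assumption in this literature) and
exposed in `tax_scenario()`. Substitution adds the cross-price terms of
the other three beverage groups; each category's change is truncated so
post-tax intake cannot go negative. Linearity makes the 30% change
exactly 1.5× the 20% change — asserted to 1e-12 in the tests.

## Anthropometric correction

Self-reported weight and height are corrected by quantile mapping against
a measured reference: on a grid of 99 probabilities (0.01–0.99), the bias
is the difference of weighted quantiles, smoothed by a cubic smoothing
spline (smoothing chosen by generalized cross-validation; a fixed `spar`
gives bit-reproducible curves), extrapolated flat beyond the grid. A new
value is placed at its quantile position by linear interpolation of the
stored self-reported quantile grid and the predicted bias is added.
Curves are fitted separately by sex; weight and height are corrected
independently, in metres, with survey-weighted quantiles (the source does
not state the grid, units or weighting; these are this package's
choices). Correcting independently is a known limitation of the method —
it aligns marginals, not the joint BMI distribution.

## The weight model

The dynamic energy-balance model tracks fat mass F, lean tissue L,
glycogen G (with 2.7 kg of bound water per kg), extracellular fluid and
adaptive thermogenesis. Expenditure is
K + γ_F F + γ_L L + δ·BW + β_TEF·EI + AT plus tissue-deposition costs;
the fat/lean partition is Forbes' p = C/(C+F) with C = 10.4·ρ_L/ρ_F. The
thermic effect of feeding is a share (0.1) of *total* intake, so the
physical-activity coefficient is δ = ((1−β_TEF)·PAL − 1)·RMR/BW — with
the package default PAL = 1.5 (all adults sedentary). All constants are
collected, with sources, in `hall_parameters()`; resting metabolic rate
uses the Livingston–Kohlstadt regressions and initial fat mass the
sex-specific age/log-BMI regressions of the adult model. The modelled
caloric change is sugar, so the carbohydrate share of the *change* is 1
(baseline carbohydrate share 0.5), which drives the fast glycogen/fluid
transient. Extracellular fluid starts at 0.32 × fat-free mass — an
initialisation convention with negligible effect on simulated weight
*changes*.

Initial states are constructed at exact energy balance (baseline intake =
PAL × RMR), so a zero perturbation yields a flat trajectory by
construction — that is a deliberate calibration choice; a
reported-intake calibration would start individuals off balance and
conflate drift with the tax effect.

Numerics: integration uses adaptive Dormand–Prince (`deSolve::ode`,
method `ode45`) with the maximum step capped at 1 day because the
glycogen sub-model has a time constant of about a day; tolerances 1e-7.
The whole cohort is integrated as one stacked system, which keeps a
10,000-adult, 10-year run under half a minute on one core. The solver is
validated against an independently coded fixed-step Euler integrator at
dt = 0.1 day (agreement within 0.01 kg at every year), and the residual
energy imbalance at year 10 is below 1 kcal/day for |Δkcal| ≤ 50. A
sanity bracket — 0.02–0.07 kg of 10-year weight change per sustained
kcal/day across adult builds — guards the overall scale.

Under equal caloric deficits the model makes *fatter* individuals lose
slightly more weight (smaller Forbes p), so with a uniform −17.3 kcal/day
women would lose marginally more than men; the male-dominant ordering
reported for Brazil arises from men's larger per-person caloric change
(higher baseline SSB intake), and that is how the pipeline produces it.

An aggregated mode (`simulate_groups()`) runs the model on group-average
pseudo-individuals (default sex × age group × tertile; the grouping is
configurable, and a mismatch with an expected count warns rather than
errors, since the published collapsing of 2×3×3 cells into "14 groups" is
not specified). Agreement of group results with microsimulation group
means is a tested property.

## Outcomes and costs

Baseline obesity prevalence (BMI ≥ 30, survey-weighted) is held constant
over the horizon — the steady-state assumption; the scenario prevalence
is read from the trajectories at each 365-day mark. Cases averted in year
y are the absolute prevalence reduction times that year's projected adult
population; the stand-in projection grows geometrically at 1%/yr from
147,852,423 adults (official projections are not reproducible here).
Year-10 "stock" accounting is used, with the yearly ledger making the
alternative (cumulative person-years) auditable.

Costs: obesity-attributable cost = 38.76 × 0.87 = US$ 33.72 billion/yr;
per case = 33.72e9 / 37.2e6 ≈ US$ 906.9/yr, inflated to US$ 942.5 in
2021 prices (the CPI factor is stored explicitly as 942.5/906.92, since
only its endpoints are published). Savings are zeroed for the first 3
years (morbidity/mortality lag), then discounted at 5%/yr with an
end-of-year convention — year y divided by (1+r)^y, summed over years
4–10; the convention is configurable because the source states only the
rate. Direct and indirect components are carried in proportion to the
published split and sum exactly to the total. Cost per case is held
constant over the horizon (population ageing would push it up, so savings
are, if anything, conservative).

Uncertainty: confidence intervals are percentile bootstrap over
individuals (default 1,000 replicates for intake tables, seeded); the
pipeline exposes `n_boot` and defaults to 0 for speed since the headline
quantities are means of large cohorts.

## Problem sizes and reproducibility

Default analysis sizes: the shipped tests estimate demand on 20,000
households (estimation sample ≈ 6,500 SSB purchasers, matching the
published zero-purchase share) and the acceptance script at the full
survey scale of 57,920 households, where the cross-price estimates are
precise enough that the substitution term stops being seed-noise; the
microsimulation cohort is 10,000 adults in the tests and 20,000 in the
acceptance script (generator default 37,689).
These sizes keep Monte-Carlo error on the headline quantities near or
below the model's structural uncertainty while a full pipeline run
completes in about a minute. Every stochastic
stage takes an explicit seed; identical configuration and seed give
byte-identical synthetic data and bit-identical results.

## Known limitations

Adults only; weight, height and physical activity constant over the
horizon; no life-table morbidity/mortality dynamics (the lag + discount
is a coarse stand-in); no tax-revenue or redistribution modelling; the
quantile correction aligns marginal distributions only; censored demand
systems (Tobit/QUAIDS) are out of scope — zero purchases enter only
through sample exclusion and price imputation.
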