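# ssbtax

Simulation of ad valorem excise taxes on sugar-sweetened beverages (SSB)
for the adult Brazilian population: from household purchase data to
obesity cases averted and discounted healthcare cost savings.

`ssbtax` is aimed at health economists and epidemiologists who want to
reproduce, stress-test or extend national SSB-tax impact models. The
restricted survey microdata such models rest on (the POF household budget
survey and the PNS health survey) cannot be redistributed, so the package
ships a seeded synthetic-data generator that emulates their structure with
known ground truth; every stage of the pipeline is therefore testable end
to end.

## The model

1. **Demand.** Own- and cross-price elasticities of four beverage groups
   (SSB; unsweetened; alcoholic; light/diet) with respect to SSB price,
   estimated by survey-weighted constant-elasticity (log-log) regressions
   with income-tertile interactions and cluster-robust standard errors:

   log q_ib = α_b + Σ_f Σ_T β_{f,b,T} log(p_f)·Tert_iT + η₁inc + η₂inc²
              + X_iθ_b + ε_ib

   Prices are unit values (expenditure / quantity); missing prices of
   non-purchasing households are imputed by enclosing-region medians
   (metro area → state → national).
2. **Scenarios.** Under a tax at rate τ with pass-through ρ, the daily
   caloric change is Δ = baseline_kcal · τ · ρ · elasticity, applied
   per person with tertile-specific elasticities; cross-price terms add
   substitution by other beverages.
3. **Anthropometry.** Self-reported weight and height are corrected to a
   measured reference survey by sex-specific quantile-difference cubic
   splines: bias(p) = Q_measured(p) − Q_selfreport(p).
4. **Weight dynamics.** Each adult's 10-year weight trajectory under the
   sustained caloric change follows the Hall adult energy-balance ODE
   system (fat mass, lean tissue, glycogen + bound water, extracellular
   fluid, adaptive thermogenesis; Forbes partition p = C/(C+F)).
5. **Outcomes and costs.** Yearly obesity prevalence (BMI ≥ 30) against a
   steady-state baseline, cases averted against population projections,
   and cost savings at a per-case annual obesity cost, with a 3-year
   no-benefit lag and 5% annual discounting.

## Worked example

```r
library(ssbtax)

cfg <- pipeline_config(seed = 7, n_households = 20000L, n_individuals = 4000L)
res <- run_pipeline(cfg)
print(res)
#> ssbtax pipeline result
#>   cohort: 4000 adults; baseline obesity (corrected): 26.3%
#>   rate20_own     mean Δkcal  -16.8 | Δweight -0.79 kg | yr-10 rel. obesity change  -7.3% | savings US$ 13.8 B
#>   rate30_own     mean Δkcal  -25.2 | Δweight -1.19 kg | yr-10 rel. obesity change -10.2% | savings US$ 19.2 B
#>   rate20_subst   mean Δkcal  -16.9 | Δweight -0.80 kg | yr-10 rel. obesity change  -7.1% | savings US$ 13.6 B
#>   rate30_subst   mean Δkcal  -25.3 | Δweight -1.19 kg | yr-10 rel. obesity change -10.2% | savings US$ 19.5 B
```

Reading the output: the demand stage estimated SSB elasticities from the
synthetic purchase file (embedded truth −1.241 / −1.186 / −1.126 by
income tertile); a 20% tax then removes ≈ 17 kcal/person/day, which the
Hall model turns into ≈ 0.8 kg of weight loss after 10 years, lowering
obesity prevalence by several percent relative to baseline; cases averted
times the annual per-case obesity cost (US$ 942.5 in 2021 prices),
lagged 3 years and discounted at 5%/yr, gives the cumulative savings.

Individual stages are plain functions, e.g.

```r
hh <- generate_households(synthetic_household_config(20000L), seed = 1)
fit_demand(hh, elasticity_spec(cluster = "state"))
#>   category tertile  estimate         se       p_value n_obs
#> 1      ssb     low -1.227517 0.04445583 7.972368e-168  6454
#> 2      ssb  middle -1.207264 0.04669826 2.284411e-147  6454
#> 3      ssb    high -1.148479 0.04042693 1.576163e-177  6454
```

The deterministic arithmetic path needs no simulation at all:

```r
reference_caloric_change_table()
#>    tertile population_millions baseline_kcal  delta_20  delta_30
#> 1      low                47.4      53.50000 -13.27870 -19.91805
#> 2   middle                49.1      74.00000 -17.55280 -26.32920
#> 3     high                51.4      86.70000 -19.52484 -29.28726
#> 4    total               147.9      71.92582 -16.86835 -25.30253
```

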