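---
title: "Forecasting type 2 diabetes prevalence from risk-factor trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting type 2 diabetes prevalence from risk-factor trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impactdm)
```

## The model and its assumptions

`impactdm` projects adult (25+) type 2 diabetes prevalence with an
annual-cycle, discrete-state Markov model stratified by sex and ten-year
age band (twelve strata).  Each cycle the living population of a stratum
is partitioned into Healthy, Obese, Smokers and Diabetes compartments;
transitions move people into Diabetes (incidence, scaled by relative
risks in the exposed states) and into two absorbing death states
(background mortality for everyone, case fatality additionally for
diabetics).  The structural assumptions are:

* **Exposure pools are exogenous.** There are no Healthy→Obese or
  Healthy→Smokers transitions; instead the Obese and Smokers compartments
  are re-anchored every cycle to the age- and sex-specific prevalence
  trends.  This sidesteps the need for initiation/cessation rates, at the
  cost of not modelling individual exposure histories.
* **Overlap resolution.** An obese smoker counts as Obese; the Smokers
  compartment holds smokers who are not obese, with prevalence
  `s(1 − o)` under independence of the two exposures.
* **PAR subtraction.** Diabetes cases attributable to an exposure
  (Levin's attributable fraction `p(RR−1)/(1+p(RR−1))`) are removed from
  that exposure's pool, so exposure compartments are non-diabetic.  The
  corrections are applied independently per exposure; no joint-exposure
  attributable fraction is used.  Survey prevalences are interpreted as
  whole-population proportions, because that is what surveys measure.
* **Zero remission.** Nothing leaves Diabetes except death.
* **No overweight state.** Only obesity (BMI ≥ 30) is modelled; the
  overweight range is deliberately outside the state space.

## Incidence decomposition and its anchoring

The incidence input is an overall rate per stratum.  Writing it as the
share-weighted sum of state-specific incidences and solving gives the
healthy-state incidence `I_h = I / (p_h + p_o·RR_o + p_s·RR_s)`, with the
shares taken from the post-partition non-diabetic pool (those are the
pools the transition rates act on).

When to evaluate that decomposition is a genuine design choice.
Re-deriving `I_h` from *each* cycle's shares pins the overall incidence
to the input value forever — the weighted sum collapses back to `I` by
construction — so the risk-factor trends would have almost no effect on
the projection, and capping obesity would change the 2022 prevalence by
a few hundredths of a percentage point.  `impactdm` therefore anchors the
decomposition at the start year (`incidence_anchor = "start_year"`, the
default): `I_h` is computed once from the start-year shares and held
fixed, so overall incidence rises as the exposed pools grow.  This is the
mechanism that lets rising obesity drive prevalence upward and produces
scenario gaps of the size reported for this class of model.  The literal
per-cycle variant is retained as `incidence_anchor = "every_cycle"` for
comparison.

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| incidence `I` | per person-year | per-stratum table | stored as proportions (printed per-1000 ÷ 1000) |
| case fatality `f` | per person-year | per-stratum table | applies to diabetics in addition to `m` |
| total mortality `m` | per person-year | per-stratum table | background, all living states |
| `RR_obese` | – | 6.74 (men), 12.41 (women) | ≥ 1 enforced |
| `RR_smoker` | – | 1.44 (both) | ≥ 1 enforced |
| `extremes_factor` | proportion | 0.20 | analysis-of-extremes shift |
| `cap_male`, `cap_female` | proportion | 0.35, 0.60 | highest observed obesity, rounded up |
| `rate_conversion` | – | `"exponential"` | `1 − exp(−rate)`; `"direct"` is `min(rate, 1)` |
| `aging_mode` | – | `"closed_strata"` | see below |

All rates live in one canonical unit (per person per year, as
proportions); printed per-1000 and percent figures are converted on
entry, which avoids silent thousand-fold errors.

## Numerical choices

* **Competing risks within a cycle** use additive hazards converted
  jointly: exit probability `1 − exp(−(r₁ + r₂))`, split `r₁ : r₂`.
  Sequential subtraction would make results depend on the order in which
  destinations are processed; the joint conversion does not.
* **Trend construction** is piecewise linear through the survey points;
  beyond the last survey the slope is `(last − first)/Δyear` across all
  surveys — the single "overall observed rate of increase", well defined
  for two or three unevenly spaced surveys; before the first survey the
  first segment's slope is carried backwards (only relevant if the model
  starts before the first survey).  All trend values are clamped to
  [0, 1] because they are proportions; the caps (`apply_cap`) are a
  separate, scenario-controlled transform.
* **Degenerate inputs.** If PAR subtraction would overdraw the
  non-diabetic pool, the exposure compartments are shrunk proportionally
  and Healthy is floored at zero; an all-diabetic stratum simply has
  empty exposure pools; a stratum whose non-diabetic pool is empty gets
  `I_h = 0` for that cycle (and, under the anchor, is anchored at the
  first cycle with a non-empty pool).
* **Fractional persons** are kept throughout; rounding happens only in
  report formatting (half-up to one decimal percent, the print style of
  the reference tables).
* **Determinism.** Iteration order is fixed (years outer, strata inner,
  canonical order), so identical inputs give bit-identical results.

## Population advancement

The data say how many people each stratum contains each year; the model
decides how the compartment mix carries over:

* `closed_strata` (default): each stratum's living compartments are
  rescaled by a common factor to the next year's exogenous count.
  Prevalence shares are preserved; there is no flow between bands.  This
  is the minimal reading of "integrating population-structure trends".
* `band_shift`: 1/10 of each band (1/15 of the 15-year-wide 75+ band,
  which exits the model) moves up one band carrying its compartment mix;
  entrants closing the 25–34 deficit arrive with that year's risk-factor
  mix and a configurable (default 0) diabetes prevalence; bands are then
  rescaled.  Neither mode is asserted as the original model's behaviour —
  the choice is exposed and documented.

## The analysis of extremes and scenarios

The extremes procedure runs the model three times: base, all
epidemiological parameters scaled by `1 − factor`, and by `1 + factor`
(default 0.20).  "All parameters" means baseline prevalence, the
risk-factor prevalences, incidence, case fatality, total mortality and
the relative risks — never the population structure.  Scaled proportions
are clamped to [0, 1]; scaled relative risks are floored at 1.  Both
extreme runs move every parameter coherently in the same direction; no
mixed-direction search for true extrema is attempted — a conservative
simplification in keeping with the method's name.  Because the start
year echoes the baseline input, the start-year band is exactly
`base ± factor·base`.

The scenario procedure compares unlimited linear obesity extrapolation
(scenario 1) against obesity capped at the highest observed value per
sex (scenario 2, caps 0.35/0.60); smoking is never capped.  Both runs
share all other inputs, so their difference isolates the capping
decision.

## The synthetic generator

No stratum-level survey table, 1992 prevalence surface or population
series is published for the original setting, so `generate_bundle()`
fabricates internally consistent inputs in the same regime: linear
obesity trends observed at three survey years (1992/1997/2005) and
smoking at two (1992/2005); age-gradient multipliers peaking at 35–44
(men) and 45–54 (women) calibrated so the peak bands hit the published
anchors (34.5% and 58.8%) at the 2005 survey; a baseline diabetes
surface increasing with age, rescaled so the population-weighted 1992
aggregate is exactly 8.5%; 6.5 million adults at start (≈555,000
diabetics at 8.5%) growing 3% per year; and the published hazard table
verbatim.  Survey-point jitter is truncated normal on the prevalence
scale — simple and range-safe.

What the generator does *not* emulate: cohort effects, non-linear or
saturating trends, sampling design and measurement error structure of
real surveys, migration, and any correlation between risk factors and
mortality inputs.  Green tests therefore demonstrate internal
correctness of the machinery (conservation, dominance, interval
ordering, oracle agreement) at realistic magnitudes — not agreement with
any real population's future.

## Validation strategy and problem sizes

The engine is validated against a seeded individual-level
microsimulation that applies the same per-cycle transition probabilities
(200,000 individuals over 30 cycles in the acceptance suite): because
every individual's year-`t` state is an independent draw, each
compartment count is binomial around the deterministic trajectory, and
agreement is required within three exact standard errors at every year.
Conservation is checked to 1e−9 relative across 100 randomized generator
bundles at the full 31-year, 12-stratum scale; the incidence
decomposition must reconstruct the overall rate to 1e−12; the
asymptotic check (no deaths, constant exposures) runs an 800-year
horizon, long enough for prevalence to pass 95% despite the PAR
re-anchoring slowing effective incidence as cases accumulate.

## Known limitations

* Exposure trends are linear by design; no smoothing, splines or
  logistic saturation (the [0, 1] clamp is the only guard).
* The PAR corrections ignore joint exposure (no obese-smoker interaction
  RR) and use the unadjusted attributable-fraction formula.
* Uncertainty intervals from the analysis of extremes are scenario
  bounds, not probabilistic intervals.
* The under-25 population, diabetes complications, treatment effects and
  costs are out of scope.
```{r session}
sessionInfo()
```
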