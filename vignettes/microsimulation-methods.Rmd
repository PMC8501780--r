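---
title: "Projecting labor-force dependency with a demographic microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting labor-force dependency with a demographic microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(lfdemosim)
```

## The model

`lfdemosim` projects a population stratified by 5-year age group, sex,
educational attainment (an ordered ladder, by default: no education,
primary, lower secondary, upper secondary, postsecondary) and labor-force
status, using a dynamic discrete-time microsimulation. The population is
represented as weighted individual cases; each case's life unfolds as a
sequence of Monte Carlo experiments in which an event occurs when its
probability exceeds a fresh uniform draw.

Time advances in 5-year steps. Within each step the events are applied in
a fixed order:

1. **Mortality** — survival ratios by age, sex and education;
2. **Education** — cohorts reaching 15–19 are broken down by an entry
   distribution of attained levels; cases then advance at most one ladder
   rung per step (never down) at ages 15–19 through 25–29, so attainment
   is final on reaching 30–34; below 15 the education variable is not
   applied;
3. **Emigration** — applied to mortality survivors only, with rates by age
   and sex; because rates are fixed, emigrant *counts* differ between
   fertility scenarios through the population sizes;
4. **Immigration** — cases with a priori numbers and characteristics are
   added, generated by the same statistical rules as the base population;
5. **Fertility** — births by age of mother; a newborn inherits the
   mother's case weight, draws a sex from the sex ratio at birth, and
   survives the partial period with a newborn survival ratio;
6. **Labor force** — every case aged 15+ is assigned active/inactive from
   the sex-specific participation model (children are `not_applicable`).

After the events, ages increment by one band (100+ absorbs). Labor-force
status is drawn at end-of-step ages, so cohorts that reach 15–19 within a
step hold a valid status in the emitted frame; this is observationally the
same cycle with the assignment done last.

## Case generation and weights

The base population is synthesized from aggregate age × sex × education
estimates. A cell with at least `oversample_threshold` persons (default
10,000) yields `round(count × sampling_fraction)` cases (default fraction
0.05%); smaller nonempty cells are oversampled to a floor of
`floor_cases` cases (default 20) to curb the Monte Carlo error of small
subgroups. Every case in a cell carries weight `count / cases`, so
weighted totals reproduce the aggregates cell by cell exactly. Rounding is
deterministic half-up — reproducibility matters more here than unbiased
stochastic rounding, and the choice only perturbs case counts by one.
Immigrant cases follow the same rules each period.

At production scale (a population in the hundreds of millions at the
default fraction, i.e. several hundred thousand cases) a single run is
enough: between-seed dispersion of the terminal indicators shrinks as
1/sqrt(cases). The test suite verifies this at a reduced scale of
20,000 cases, where the relative dispersion across seeds is already below
1.5%; package tests otherwise run at 1,000–100,000 cases and 1–11
projection steps to keep the suite fast.

## Common random numbers

Scenario comparisons (the default experiment pairs a low fertility
scenario, TFR 0.8, against a high one, TFR 1.7, all other assumptions
shared) should differ only through the assumptions, not through sampling
noise. Every uniform draw is therefore a pure hash — a SplitMix64 chain —
of `(seed, individual id, event, period, repetition)` rather than a
sequential RNG stream. Ids are stable across scenarios for the base
population and for immigrants (whose profile is shared), so every
individual alive in both scenarios experiences *identical* mortality,
education, emigration and participation outcomes. Consequently the
age × sex × education × activity structure of the population old enough to
predate the scenario split (ages 25+ by year 25 of a projection started
in 2015) is bit-identical between scenarios, not merely equal in
distribution. Newborn draws are keyed by the mother's id and a birth
index, so extra births in one scenario never perturb anyone else's
outcomes.

Births per woman per step are Poisson with mean 5 × ASFR (inverse-CDF from
the woman's keyed uniform). A Bernoulli would cap births at one per
5-year step and bias high-fertility scenarios down; the Poisson admits
multiple births per step with the right expectation. The sex ratio at
birth defaults to 1.05 males per female and is configurable.

## Calibration models

**Participation.** For each sex separately,

logit(P) = β₀ + β₁·AGE + β₂·AGE² + β₃[edu] + β₄[edu]·AGE + β₅[edu]·AGE²,

with AGE the band midpoint coded as `(mid − 45) / 5` (centering and
scaling condition the quadratic; the coding is recorded on the fitted
object so coefficients stay interpretable) and education categorical with
full age interactions. The quadratic gives the inverse-U age profile —
lower participation for young adults still in school and for older
persons — and the interactions let the retirement pattern differ by
attainment. Fits are maximum-likelihood `glm` logits; complete separation
and non-convergence raise errors naming the stratum. Nagelkerke
max-rescaled R² and the c-statistic are attached for comparability with
survey-based fits. Participation parameters are held constant over the
projection, so aggregate participation changes only through population
composition — notably the better-educated cohorts, with higher female
participation, replacing older ones.

The model is calibrated on survey ages 15–74. Ages 75+ receive rate 0
rather than an extrapolated quadratic, which would be unsafe outside the
window; 15–19 uses the fitted value.

**Productivity weights.** Wages of labor-force members are modeled as

ln E(WAGE) = β₀ + β₁[edu] + β₂[age band] + β₃·sex + β₄[survey year],

fitted by Poisson regression with log link. The response is continuous, so
this is the quasi-likelihood analogue (identical point estimates;
`quasipoisson` avoids spurious non-integer warnings). The productivity
factor of education level *e* is W_e = exp(β₁[e]), with the reference
category — upper secondary — at W = 1 exactly by coding. Year effects are
absorbed by β₄ and never enter the weights; the tests verify invariance
under relabeling survey years. Age and sex enter additively as controls
only, with no interactions.

## Indicators

With weighted counts,

* **ADR** = (population < 15 + population 65+) / population 15–64;
* **LFDR** = inactive / active, where *inactive* is the population out of
  the labor force irrespective of age — children count in the numerator
  even though their individual status is `not_applicable`;
* **PWLFDR** = I / Σₑ Wₑ·Aₑ, the LFDR with each active person weighted by
  the productivity factor of their education. A value of 1 means one
  inactive per productivity equivalent of an upper-secondary worker.
  Under unit weights PWLFDR reduces to LFDR exactly.

Series are normalized to a base period (base = 1) for cross-scenario
comparison. Pyramid summaries collapse the ladder to three tiers: below
upper secondary = low, upper secondary = medium, above = high.

The education ladder defaults to five categories but is configurable
(e.g. splitting postsecondary into six levels); nothing is merged
silently — the ladder and its reference level are explicit in every
configuration object.

## The synthetic world

`synthetic_world_spec()` generates every input with known ground truth:

* a **stylized aging pyramid** — mid-age bulge, recent cohorts roughly
  half the bulge size — deliberately *not* a copy of any country's
  estimates;
* an **education gradient**: the youngest adult cohorts hold a much more
  educated composition than the oldest, interpolated between the two and
  scaled by `education_gradient` (0 gives identical compositions);
* **schedules**: survival ratios declining with age on a logit-cubic,
  with a female advantage, an education gradient and slow improvement
  over periods; a bell-shaped fertility schedule over ages 15–49
  normalized so 5 × Σ share = 1; young-adult-peaked emigration; an
  immigrant inflow fixed at 40% of the base period's expected outflow, so
  net migration stays negative under the defaults; entry distributions
  tilting slowly toward higher attainment;
* **survey microdata** with activity drawn from the true participation
  logit and wages from the true log-wage model. The true education premia
  span 0.36 (no education) to 2.03 (postsecondary) around the
  upper-secondary reference. Wages are Poisson at the estimator's own
  family; `wage_dispersion > 1` switches to negative binomial to
  exercise estimator robustness under misspecification.

What passing tests on this world demonstrate: the mechanics (conservation,
ordering, common random numbers, estimator recovery, the composition-driven
dampening of the LFDR and PWLFDR relative to the ADR). What they cannot
demonstrate: agreement with any real country's trajectories, which depends
entirely on user-supplied estimates and schedules; survey features such as
sampling weights, clustering and item nonresponse are also not emulated
(the fitting functions are unweighted, matching the fixed model forms).

## Numerical choices and degenerate inputs

* Case-count rounding: deterministic half-up, minimum one case per
  nonempty cell.
* Uniform draws lie strictly inside (0, 1) (53-bit mantissa, half-ulp
  offset), so probability-0 events never fire and probability-1 events
  always do.
* Keyed Poisson draws use `qpois(u, λ)`; λ = 0 gives 0 births.
* Empty frames pass through every step unchanged; indicator functions
  raise on zero denominators rather than returning NaN.
* Schedule lookups error on a missing stratum *naming it*, except
  education transitions, where an absent row means probability 0 (the
  tables are only required at ages 15–29).
* Newborn partial-period survival comes from its own schedule; setting it
  to 1 makes newborns survive the birth period fully.

## Limitations

* No continuous-age or annual-step variant; the 5-year grid is structural.
* No kinship beyond the mother→newborn weight inheritance; no regional
  breakdown; no time-varying participation parameters; labor-force status
  is redrawn each period from the cross-sectional model without state
  persistence or lagged-fertility covariates.
* The productivity weights proxy productivity by wage differentials under
  a competitive-market assumption; they carry no monetary GDP
  translation.
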