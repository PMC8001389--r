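---
title: "Methods: egg thermal biology, from cohort survival to oviposition windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: egg thermal biology, from cohort survival to oviposition windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eggtherm` analyses egg-cohort incubation experiments run across a
factorial grid of constant temperatures and relative-humidity (RH)
regimes, and carries the fitted thermal parameters into field phenology.
This vignette documents the statistical models, the assumptions and
numerical choices behind them, and what the synthetic-data generator does
and does not emulate.

## Data model

The observational unit is a daily reading of an egg cluster: counts alive
(split by external colour stage: yellow, brown, head-capsule/"blackhead"),
cumulative hatched, and cumulative dead. Clusters of 10–15 eggs, 20
replicate clusters per condition, and a grid of 8 temperatures (8–36 °C in
4 °C steps) × 3 RH bands (high 90–100%, medium 50–75%, low 10–35%) is the
reference design (`design_conditions()`, 24 conditions).

`derive_fates()` converts daily tables into per-egg records. Events are
assigned to the day of first detection: cages are inspected daily, so
sub-day timing is unobservable and ages are integers in days. Eggs still
alive at an observation horizon become right-censored — an extension
beyond the reference experiment (which ran all eggs to completion) needed
for horizon-truncated simulations. Cluster-level colour counts
under-determine which egg was in which stage, so per-egg stage durations
are only populated when per-egg ground truth (the generator) or long-format
input supplies them.

## Survival

Death of the egg is the event of interest; a hatching egg leaves the egg
stage *alive*, so hatched eggs are right-censored at their hatch age. This
convention makes *lx* literally "the probability at laying of being alive
at age *x*". The product-limit estimator and the k-sample log-rank test
are implemented directly: at each distinct death age the observed deaths
per group are compared with their hypergeometric expectation given the
risk sets, deaths are processed before censorings at tied ages, and the
χ² statistic is the quadratic form over k−1 groups (solving the covariance
block directly, with a Moore–Penrose generalized inverse as fallback when
it is singular), df = k − 1. With zero deaths the statistic is 0 and
p = 1.

Eggs are treated as independent subjects. Within-cluster correlation is
ignored — this matches the degrees of freedom conventionally reported for
such experiments, and cluster frailty is out of scope. Pairwise regime
comparisons report raw per-pair p-values without multiplicity adjustment,
again following field convention for these summary tables.

## Development time

Only eggs that completed development enter duration analyses; conditions
where everything died are *absent* from summaries, not zero.

Hatch age in whole days is modelled as a Poisson count with a log link
(`stats::glm`, IRLS to deviance change 1e-8, at most 100 iterations).
Durations are not true counts, and the Poisson assumption is kept
deliberately because it is the standard treatment in this literature; the
deviance/df dispersion is reported as a diagnostic but not corrected.
Per-term χ² values come from Type-II analysis of deviance
(`car::Anova(type = 2, test = "LR")`): each term is tested against the
model containing all other terms of equal or lower order, the appropriate
default for unbalanced factorials (cohorts lose unequal numbers of eggs to
death). The default formula is `hatch age ~ factor(temperature) * RH`,
dropping factors without observed variation.

Post-hoc groupings follow the Tukey HSD logic on the linear-predictor
scale. For a Poisson log-link model the level mean on that scale is
`log(mean(y))` with variance `1/sum(y)`; pairs are compared against
`qtukey(1 - alpha, k, df_residual)/sqrt(2)` and a compact letter display
is built greedily over the sorted means (maximal runs whose extremes do
not differ share a letter). The scale choice is the closest defensible
analogue of pairing an HSD routine with a Poisson GLM, and `alpha`
defaults to 0.05.

## The thermal model

Development rate is the reciprocal of the *per-condition mean duration*
(not the mean of per-egg reciprocals — the convention in degree-day
studies). Ordinary unweighted least squares of rate on temperature, per RH
regime, gives slope *b* and intercept *a*, from which

* lower development threshold **T₀ = −a/b** (°C), and
* thermal constant **K = 1/b** (degree-days).

The linear model only describes the suboptimal range, so by default
temperatures above the regime's empirical rate maximum are excluded
(under the reference design this removes the 36 °C point, where the rate
declines again); `exclude_supraoptimal = FALSE` keeps everything. A fit
with non-positive slope is flagged invalid and yields no thermal
parameters rather than a nonsensical negative K. Weighting by condition
sample size is deliberately not applied: unweighted OLS reproduces the
simple linear-model procedure this analysis standardises.

## Phenology

Degree-days use the temperature-mean method: each day contributes
`max(0, mean temperature − T₀)`, with no upper development threshold.
`weekly_mean_series()` optionally smooths multi-year series into a weekly
climatology (calendar weeks of 7 days from 1 January, the final short week
pooled into week 52) expanded back to constant-within-week daily values.

Accumulation for a clutch laid on date *d* starts the day after laying:
this makes the constant-temperature forecast exactly
`ceiling(K/(T − T₀))` days after laying and keeps the accumulator
consistent with the continuous prediction `K/(T − T₀)` to within one day
of discretisation. The `include_lay_date` switch restores the
day-of-lay-counts convention if wanted.

The oviposition window is back-calculated from field stage records using
stage durations at a reference temperature (8 °C, the closest constant
temperature to winter field means):

* **start** — earliest of (first larva date − total egg duration − assumed
  larval age at detection, default 0, i.e. newly hatched) and (first
  head-capsule record − yellow − brown durations); clipped to be no
  earlier than the first reproductive-adult catch when adult records
  exist, since adults must precede eggs.
* **end** — the date of the last yellow-cluster record. That cluster was
  laid at most one yellow-stage duration earlier, so the true end lies in
  `[end − yellow, end]`; the interval is reported (`end_lay_earliest`)
  rather than collapsed.

## The synthetic-data generator

The generator exists so that every downstream stage is testable without
the original laboratory data, which are not deposited. Per egg: a
Bernoulli draw from a per-condition survival surface decides hatch versus
death; hatched eggs draw an integer duration from a discretised gamma
(shape `1/CV²`, minimum 1 day — positive, right-skewed, matching integer
daily recording; no distributional form is prescribed by the reference
analysis) with mean `K/(T − T₀)`; dead eggs die at an age uniform on
`[1, would-be duration]` (a maximum-entropy placeholder — no death-timing
distribution is reported — and a documented, swappable policy); colour
stages partition each duration by fixed fractions with largest-remainder
rounding. Daily tables are the exact tally of the per-egg truth, so the
readers, validators and `derive_fates()` reconcile with the generator by
construction.

Defaults are the study conditions: per-regime thermal parameters
(low 3.30 °C / 246.14 DD, medium 3.40 / 230.83, high 3.82 / 209.05),
duration CV 0.1, stage fractions (0.30, 0.45, 0.25) making brown the
longest stage everywhere, and a ×1.3 duration inflation above 32 °C so
development slows again at 36 °C instead of following the linear
extrapolation. The survival surface is an explicit 24-cell probability
table rather than a logistic-with-offsets family: the observed response
patterns *cross* (medium RH survives best at the 8 and 36 °C extremes,
high RH is best at 12–20 °C, low RH is clearly worst at 24–32 °C), which
regime offsets alone cannot produce. The cells are calibrated once to
those ordinal patterns and to the qualitative anchors (near-total survival
at 8 °C outside the dry regime, roughly half under dry-cold conditions, a
sharp drop at 32–36 °C); no per-cell percentages are published to anchor
to, so only ordinal behaviour is meaningful.

The temperature generator is a seasonal sinusoid (default mean 15 °C,
semi-amplitude 9 °C, coldest day 15 January — January ≈ 6 °C, July ≈
24 °C, an Ebro-Valley-like Mediterranean profile) plus stationary AR(1)
noise (sd 1.5 °C, ρ = 0.6). A symmetric sinusoid underestimates the warm
early autumn of the real region slightly, so forecast examples hatch
first-week-of-October clutches in ~2.5 weeks rather than 2; tests
therefore assert a two-to-three-week band. Field records are generated
deterministically: one cohort laid per day across the window, progressing
through stages at the reference durations, with reproductive-adult records
from the window start.

What passing tests show, and what they do not: the generator reproduces
the *structure* of real cohort data (factorial design, censoring,
integer ages, cluster tallies, ordinal survival patterns) but not its
cluster-level frailty, observation gaps, or any temperature–humidity
interaction in durations; parameter-recovery results therefore validate
the estimators, not the biology of any particular population.

## Numerical choices and problem sizes

* Log-rank covariance: direct solve of the (k−1)×(k−1) block,
  `MASS::ginv` fallback; statistics clamped at 0 against floating-point
  negatives.
* GLM convergence: deviance epsilon 1e-8, 100 iterations, hard error on
  non-convergence.
* Letter display ties: remainders in the stage partition break toward the
  earlier stage; CLD assumes monotone non-significance within runs of
  sorted means (exact for equal standard errors, the usual approximation
  otherwise).
* Validation: readers fail with the offending column, cluster or date
  named; the pipeline validates its configuration before any stage runs.
* Test problem sizes, chosen to exercise the asymptotics the estimators
  rely on while keeping the default suite around two minutes: 100
  brute-force log-rank comparisons, 5,000 null simulations for the type-I
  error check (2 × 50 eggs each), 200 parameter-recovery replicates at the
  full per-regime design (8 temperatures × 20 clusters × 10–15 eggs), 100
  synthetic oviposition-window recoveries, and convergence checks at
  ~10,000 eggs.

## Known limitations

* No nonlinear rate models (Brière, Lactin, Logan, Sharpe–Schoolfield) and
  no upper-threshold estimation; the supraoptimal regime is excluded, not
  modelled.
* No clustered/frailty survival variance and no Cox or AFT alternatives.
* Overdispersion of durations is reported, not corrected
  (no quasi-Poisson/negative-binomial fits).
* The low-RH printed coefficient pair in the reference table implies a
  threshold (≈3.44 °C) slightly different from the printed 3.30 °C —
  rounded inputs cannot reproduce it; derivations here always come from
  the coefficients actually supplied.
* Oviposition-window accuracy is bounded by field sampling frequency at
  the start and by one yellow-stage duration at the end; both bounds are
  reported, not hidden.
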