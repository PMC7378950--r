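---
title: "Fitting and comparing spring phenology models across observation scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting and comparing spring phenology models across observation scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscale)
```

## The problem

Spring plant phenology — the timing of budburst and first flowering — is
monitored in two very different ways. Intensive programmes revisit the same
individuals at a single site every 3–7 days for many years; broad-scale
(citizen-science style) programmes cover hundreds of sites but visit each
plant sparsely and irregularly, with whole years dropping out. Both produce
*status records*: repeated yes/no assessments of whether a phenophase is
present on a plant. phenoscale implements the full workflow for asking
whether process-based phenology models fitted to the two data types agree —
in their parameters, in their predictions, and in their out-of-sample
errors — and for exercising that workflow end to end on synthetic data with
a known generative truth.

## Event inference from status records

An event day is never observed directly; it is interval-censored between
the first "yes" and the most recent preceding "no". The cleaning rules are:

* "unsure" records are dropped before anything else;
* duplicate records of one plant on one day resolve to "yes" (counted and
  reported);
* per individual, phenophase and year, the *first* "yes" defines the event;
  it is kept only when the preceding "no" lies within `max_gap_days`
  (default 30; 15 as a sensitivity variant) — otherwise the censoring
  window is too wide to locate the event;
* the event day of year (DOY) is the midpoint of the no/yes pair.
  Half-integers are kept: rounding would discard information and RMSE is
  real-valued anyway;
* budburst events past DOY 172 and flowering events past DOY 213 are
  removed as likely outliers ("past" is strict, the cutoff day itself
  survives);
* species × phenophase groups with fewer than 30 events are dropped. The
  count happens *after* the cutoff filter, so it reflects events actually
  available for fitting. The boundary is `>= 30` by default with a strict
  `> 30` variant (`rule = "gt"`), since usage varies between descriptions
  of this filter.

Individuals are never pooled to a site-level record; intra-site variability
is part of the signal.

## The model set

Eight predictors map a daily mean temperature series (and derived
covariates) to a predicted event DOY. Two are statistical baselines:

* **Naive** — the historical mean DOY ($\overline{DOY}$), ignoring climate;
* **Linear** — $DOY = \beta_1 + \beta_2\,T_{mean}$, with $T_{mean}$ the
  mean daily temperature over 1 January–31 March (DOY 1..90 in all years;
  29 February is treated as an ordinary day of the sequence).

The remaining six share a thermal-forcing skeleton: daily temperature
$T_i$ is transformed into forcing units $R_f(T_i)$, accumulated from a
start day $t_1$, and the event occurs on the first day $t$ with
$\sum_{t_1}^{t} R_f(T_i) \ge F^*(t)$:

| model | forcing $R_f(T_i)$ | requirement | free parameters |
|---|---|---|---|
| GDD | $\max(T_i - T_{base}, 0)$ | $F^*$ | $t_1, T_{base}, F^*$ |
| Fixed GDD | $\max(T_i, 0)$ | $F^*$ | $F^*$ |
| Alternating | $\max(T_i - 5, 0)$ | $a + b\,e^{c\,NCD(t)}$ | $a, b, c$ |
| Uniforc | $1/(1 + e^{b(T_i - c)})$ | $F^*$ | $t_1, b, c, F^*$ |
| M1 | $\max(T_i - T_{base}, 0)$ | $(L(t)/24)^k F^*$ | $t_1, T_{base}, F^*, k$ |
| MSB | $\max(T_i - 5, 0)$ | $a + b\,e^{c\,NCD(t)} + d\,T_{mean}$ | $a, b, c, d$ |

$NCD(t)$ is the number of chill days — days with mean temperature strictly
below 0 °C — between 1 January and day $t$, re-evaluated daily. $L(t)$ is
the photoperiod in hours, computed with the CBM day-length model of
Forsythe et al. (1995) with daylight coefficient $p = 0$ (sunrise/sunset at
the centre of the solar disk); the model is accurate to a few minutes at
the mid-latitudes in scope, and polar latitudes (|lat| > 66°) are rejected
rather than approximated.

Numerical conventions, chosen once and applied everywhere:

* threshold comparisons use $\ge$ — the event is the first day *reaching*
  the requirement;
* $t_1$ is an integer day; continuous optimiser proposals are rounded
  before prediction. Negative $t_1$ (a previous-autumn start) is allowed,
  with default bounds $[-30, 120]$, and temperature series therefore span
  DOY $-90..250$;
* a model that never meets its requirement within the series range returns
  the no-event marker (`NA_real_`), never a day. The fitting objective maps
  it to a fixed 1000-day residual: far beyond any real residual, finite, and
  steep enough to push the optimiser away from degenerate corners of the
  parameter box;
* the Uniforc slope $b$ is bounded negative, so the sigmoid rises with
  temperature and saturates at one forcing unit per warm day;
* one published statement of the M1 forcing clamps it at 5 units
  (`max(Ti - Tbase, 5)`); the GDD analogy and the model's source imply a
  floor of 0. The package defaults to 0 and exposes
  `control = list(m1_forcing_floor = 5)` to reproduce the clamped variant;
* chill days use strict $T_i < 0$; a day at exactly 0 °C is not a chill
  day.

These six predictors are verified against an independent day-by-day
reference loop on a thousand randomized series, and against each other via
their limit identities (M1 with $k=0$ is GDD; MSB with $d=0$ is
Alternating; Alternating with $b=0$ is GDD with $t_1=1$, $T_{base}=5$,
$F^*=a$; Fixed GDD is GDD with $t_1=1$, $T_{base}=0$).

## Fitting

Parameters are estimated by differential evolution (via DEoptim,
rand/1/bin with per-vector dither), minimising the training RMSE of the
predicted event day. Defaults: population 30, mutation dithered in
$[0.5, 1]$, crossover 0.7, at most 500 generations with a relative
improvement stop of $10^{-3}$ over 50 generations. The bounds span
published fits while keeping the search compact (e.g. $F^* \in [0, 1000]$,
$T_{base} \in [-10, 15]$). Everything is reproducible from a single seed.

Uncertainty comes from a bootstrap: the model is refit on (by default) 250
n-out-of-n resamples of the training events. Each resample has its own
derived seed, but all refits share one *optimiser* seed — a refit is then a
pure function of its resampled dataset, so a degenerate dataset of
identical observations provably yields zero parameter spread. Reported
predictions are the mean of the per-bootstrap predicted days; bootstrap
members predicting no event are excluded from that mean (and only if all
members fail does the no-event marker propagate). A failed refit is retried
once on a fresh resample, then recorded as missing.

Before fitting, 20% of events in each species × phenophase group are held
out (banker's rounding on $0.2 n$, at least one event, refusing groups
under five events). Holdout RMSE — not information criteria — is the
package's only measure of predictive skill, and both the bootstrap-mean and
the point-fit prediction routes are exposed (`prediction_method`), since
either is defensible for evaluation.

A caution worth stating explicitly: models of this family are weakly
identifiable. On a series with $T_i = 0$ for days 1–4 and 10 °C after, GDD
with $(t_1{=}1, F^*{=}10)$ and $(t_1{=}5, F^*{=}5)$ predict the same day.
Training RMSE can collapse to zero while individual parameters wander along
a ridge; parameter agreement and prediction agreement are therefore
separate questions, which is exactly what the comparison stage measures.

## Comparing two model collections

Given one collection fitted to intensive data and one to broad-scale data,
three comparisons are produced:

1. **Parameters** — per model and parameter, the bootstrap-mean values are
   paired across species × phenophase groups and summarised by the
   identity-line coefficient of determination
   $R^2 = 1 - \sum (y_i - x_i)^2 / \sum (y_i - \bar y)^2$. This measures
   agreement with the 1:1 line, not linear association, and is negative
   when the pairs agree worse than a constant at $\bar y$ would. Which
   collection anchors the variance in the denominator is a genuine choice;
   the package anchors on the broad-scale collection and reports the
   reversed ordering alongside (`r2_ab`, `r2_ba`).
2. **Predictions** — paired predictions for every holdout event,
   summarised by the same statistic, separately for events at intensive
   and at broad-scale sites; no-event predictions are excluded pairwise.
3. **Errors** — per model and group, the difference in holdout RMSE
   (intensive-derived minus broad-derived model) on the *same* events,
   with a two-sided one-sample t test of mean zero. Differences of zero
   variance are reported as degenerate rather than tested. No
   multiple-testing correction is applied across models; the raw p values
   are reported as such.

A species monitored at two intensive sites contributes separate pairs (one
per site), and its intensive-vs-intensive errors are compared within site.
Pearson correlations are available alongside all of these.

## The synthetic study generator

The generator is the package's stand-in for a continental observation
network plus gridded climate, built to reproduce the *statistical
structure* the analysis depends on, not the climate itself:

* **Temperature** — a latitude-lapsed sinusoid with white noise:
  $T_i(d) = M(lat) + A \cos(2\pi (d - d_{peak})/365) + \varepsilon$,
  defaults $M = 12$ °C at 40° N with $-0.8$ °C per degree latitude,
  $A = 12$ °C, peak at DOY 200, noise sd 3 °C, over DOY $-90..250$. This
  yields winters near 0 °C and spring forcing ramps of realistic size for
  temperate North America. There is deliberately no temporal
  autocorrelation — the simplest structure the forcing models respond to —
  and that is a known limitation: real weather's warm spells make
  accumulated forcing more variable than this generator does.
* **Truth** — a configurable generative model (default Fixed GDD,
  $F^* = 200$, which places budburst in April–May at these climatologies).
  Species differ by scaling the threshold-like parameter (±30% across 4
  species by default); sites can additionally vary around the species
  value (`param_spatial_sd`), which is the mechanism that decouples
  single-site from range-wide parameter estimates. Individuals scatter
  around their site-year's predicted day with sd 2 days. Noise is applied
  to the realised day, not the forcing threshold — simpler, and sufficient
  to create the censoring and fitting problems the pipeline must handle.
* **Campaigns** — intensive sites revisit each individual at a fixed
  interval drawn from 3–7 days; broad-scale sites visit on random days
  (daily probability 1/14) and skip whole individual-years with
  probability 0.3. Visits before the true day record "no", on or after it
  "yes". Spatially clustered sampling bias and observer error are not
  modelled.

Defaults of 2 intensive versus 20 broad-scale sites over 6 seasons mirror
the few-intensive/many-sparse contrast of real monitoring. Every stream
(site placement, weather, spatial parameter draws, individual noise, visit
schedules) derives deterministically from one master seed, so a study is a
pure function of its configuration.

Because the generator's truth is known, passing tests demonstrate that the
pipeline recovers what it should *under these assumptions*: they validate
the machinery (inference, fitting, comparison), not the meteorological
realism of any particular climate product, and say nothing about model
adequacy for real species.

## What the pipeline reproduces

`run_pipeline()` chains simulate → clean → split → fit both collections →
compare, stamps every artifact with the seed and a configuration hash, and
is byte-reproducible given both. The package's own evaluation uses problem
sizes chosen to exercise every code path at desk scale: oracle equivalence
on 1000 random series; parameter recovery on a 200-event study (fitted
$F^*$ lands within a fraction of a percent of the generating 200, and GDD /
Uniforc holdout RMSE sits near the 2-day noise floor); and a ten-replicate
transfer experiment (2 intensive vs 20 broad-scale sites, site-varying
$F^*$) in which the mean RMSE difference is negative on intensive holdouts
and positive on broad-scale holdouts — each data type predicts itself best,
the central cross-scale asymmetry, with smaller fitting settings
(population 15, ≤80 generations, 2 bootstrap reps, point predictions) that
leave the sign pattern intact. `scripts/acceptance.R` recomputes all of
these from scratch.

## Known limitations

* No chilling-dependent two-phase models (Unichill-style) and no
  precipitation drivers; desert flowering phenology driven by rainfall is
  outside this model family.
* The generic metric binariser (`binarize_intensive_metrics`, metric >
  threshold → "yes") stands in for protocol-specific conversions of
  intensive monitoring metrics.
* Gaps in temperature series are errors, not interpolation targets.
* The identity-line $R^2$ orderings can differ noticeably when the two
  collections have very different variances; both are reported for that
  reason.
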