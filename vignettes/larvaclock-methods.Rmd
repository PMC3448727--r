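---
title: "Methods: photoperiod schedules and seasonal growth-rate analysis"
author: "larvaclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photoperiod schedules and seasonal growth-rate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaclock)
```

## The problem

Temperate insects use day length as their seasonal clock. Common-garden
experiments that probe this rear larvae from different latitudes under
chamber photoperiods mimicking particular latitudes, measure individuals a
handful of times across a simulated season (including an artificial winter),
and ask whether populations differ in intrinsic growth rate and in their
plastic response to the photoperiod cue. `larvaclock` packages the three
quantitative layers such an experiment needs:

1. a **photoperiod engine** that converts latitude and date into the light
   phase a chamber should be programmed with,
2. a **growth-trajectory statistic** turning four size measurements per
   individual into season-specific growth rates, and
3. the **inferential models** (nested mixed-effects ANOVAs with Wald
   chi-square tests) matched to the hierarchical sampling design,

plus a **molt-based simulator** of the whole design, so that each layer can
be validated, calibrated and power-checked without access to field data.

## Light phase and the civil-twilight rule

The engine computes, for a latitude and date, the hours the sun spends above
a given altitude via the classical hour-angle formula, with solar declination
from the low-precision fractional-year (Spencer) expansion. The *light
phase* of a chamber is daylight — sun above `rise_set_altitude`, default
−0.833° (refraction plus the solar radius) — plus a fraction
(`twilight_fraction`, default 0.5) of each civil twilight, the interval
during which the sun sits between −6° and −0.833°.

One boreal subtlety is handled explicitly: in midsummer at high latitudes
the sun sets but never reaches −6°, so *the entire dark period is civil
twilight*; the rule then adds `twilight_fraction × (24 − daylight)` and the
day is flagged `all_night_twilight`. This regime is what makes a 64°N July
chamber setting exceed 22 light hours even though actual daylight is only
about 20.2 h.

Accuracy: the Spencer declination is good to about 0.2°, i.e. a few minutes
of light phase at 67°N and less at mid-latitudes. The test suite holds the
engine within 5 minutes of an independent oracle (Meeus-style ecliptic
longitude declination with minute-grid quadrature) across latitudes up to
67° over 2010–2011. That is ample for chamber programming, which is rounded
to the minute anyway (`to_hmm()`/`from_hmm()` convert between decimal hours
and the conventional hours.minutes notation). Durations are computed in
apparent solar time at the stated meridian; clock times of sunrise and
sunset, longitude offsets and time zones are deliberately out of scope.

`experiment_schedule()` composes the full treatment program: daily tracking
from 10 July, a step down to 16 °C the day before winter, a 14-day total
blackout at 5 °C, and a spring restart in which the calendar jumps forward —
the first spring day maps to 9 April of the following year and advances
daily thereafter, with 15 days at 16 °C before returning to 22.5 °C. Chamber
practice of reprogramming only on Saturdays is available as
`update = "weekly"`; the default evaluates the sky exactly on each mapped
date, which is also what the schedule's published anchor values correspond
to.

## The growth-trajectory statistic

Each individual is measured four times at 42-day intervals on a
*winter-excluded* age axis (`winter_adjusted_age()` freezes age across the
winter window, since no growth occurs then). Growth is saltatory — size is
constant within an instar and jumps at molts — so adjacent-interval ratios
are not independent growth-rate estimates. Instead the whole trajectory is
modelled as a cubic on log head width,

\[ L_i(t) = b_0 + b_1 t + b_2 t^2 + b_3 t^3 , \]

which with four measurements interpolates exactly, and the two seasonal
rates are the derivative \(b_1 + 2 b_2 t + 3 b_3 t^2\) evaluated at day 21
(mid summer/fall) and day 105 (mid spring). Both anchors are configuration
(`season_anchors()`). Numerical choices: the fit is performed on centred age
for conditioning and mapped back, so reported coefficients are on the raw
age axis and the fitted curve is identical either way; natural log is the
default base (the base only rescales rates, and the base used is recorded on
the output); individuals with fewer than four distinct ages get a
reduced-degree polynomial and are flagged, those with fewer than two are
excluded and counted.

The day-0 value is, by protocol, the family-mean hatchling size (individual
hatchlings are too small to measure repeatedly), and the same family mean
serves as the hatch-size covariate; day-84 size is the spring covariate.

## Inferential models

The growth-rate records form a three-level hierarchy: regions (fixed
interest), sub-populations within regions, families within sub-populations,
individuals within families, with families split across both photoperiod
treatments. `fit_seasonal_model()` fits, via `nlme::lme`,

* fixed: `region * photoperiod` (optionally plus a screened covariate),
* random: intercepts for sub-population and family-within-sub-population,

with REML by default (ML available) and Type II Wald chi-square tests per
fixed term via `car::Anova` (Type III available). Wald asymptotics are used
as-is: there is no agreed small-sample degrees-of-freedom correction for
mixed models, and none is attempted. Random-effect variances are reported as
variance components but not significance-tested — the design has too few
sub-populations for that to be meaningful. Covariates are screened inside
the full mixed model and retained only when significant at the screening
level (default 0.05); the alternative of screening in a covariate-only model
was considered and rejected as less faithful to how the final model is used.
Note that when the generator's latitudinal hatch-size cline is active, the
hatch-size covariate is genuinely correlated with region, and retaining it
absorbs part of the region signal — an instance of the usual
covariate-confounding caveat, visible in the demonstration runs.

Convergence is handled by a cascade: the nested fit with `nlme`'s default
optimizer, then with `optim`, then a sub-population-only random structure,
finally a fixed-effects model; any step down is flagged and logged. A fit
whose residual variance collapses to (numerically) zero is treated as
singular and passed down the cascade as well, where degenerate fixed-effects
tables are resolved exactly from Type II sums of squares (a non-zero term
sum of squares against a zero residual is infinitely strong evidence; a zero
one is none). The choice of optimizer matters more than it might seem: with
a forced Nelder-Mead the boundary variance estimates under a true-zero
variance component stall high, which measurably deflates the type-I rate of
the between-population region test; the default-first cascade restores
nominal calibration.

Adult field sizes use `region * sex` with a population random intercept, and
report the male − female head-width contrast averaged over regions with its
standard error. Hatchling sizes use a classical one-way ANOVA. The
hatch-size/growth regressions are OLS within the treatment group in which
hatchlings were measured (individual-level by default; a family-mean
aggregation mode is provided, as the appropriate unit is arguable).

## The synthetic-data generator

`simulate_experiment()` emulates the full design: 3 regions with 3/4/1
sub-populations and 14/14/5 families, clutches split across the two
photoperiod treatments, 5 replicates per family per treatment (165 larvae
per treatment), hatchling size increasing with latitude of origin, and field
adults with the per-site, per-sex sample sizes of the original collection.

Growth is generated mechanistically as a **molt process**: width multiplies
by the increment ratio `r` (default 1.25, a typical odonate head-width molt
increment — a documented default, not a measured value) at molt events
arriving as a Poisson process with rate `rate / log(r)` per day, so the
expected log-width slope equals the target rate exactly. The rate switches
from the summer/fall to the spring value at age 63 (the winter midpoint on
the excluded-age axis), and the winter contributes no molts by construction.
Measurement error is multiplicative lognormal (SD 0.01 on the log scale).
An individual's target rate in each phase is the region × treatment cell
mean plus sub-population, family and individual Gaussian deviations
(defaults 5·10⁻⁴, 10⁻³, 2·10⁻³ log-mm/day).

Because published growth rates are not available, the default cell means are
free parameters chosen once, at design time, to reproduce the qualitative
latitudinal pattern at realistic signal strength: summer/fall rates decrease
with latitude of origin, the northern photoperiod accelerates growth with
the gap largest in the central region and negligible in the northernmost;
in spring the central region reverses (faster under the southern
photoperiod) while the high-latitude regions do not — a crossing
interaction. The magnitudes (fall, southern/northern photoperiod: central
0.010/0.020, northern 0.009/0.014, northernmost 0.008/0.009; spring: central
0.014/0.008, northern 0.008/0.013, northernmost 0.0085/0.013 log-mm/day)
were set against the molt process's intrinsic noise — at `r = 1.25` the
per-individual anchor-slope SD is about 0.0085 log-mm/day — so that the
study-sized experiment detects the pattern with test statistics of the
order a real experiment of this design reports.

The truth table stores, per individual, both the latent phase rates and the
*expected anchor slopes*: the slopes at day 21/105 of the cubic through the
expected log trajectory. The latter is the correct estimand for
recovery checks, because a cubic interpolating a piecewise-linear expected
trajectory does not have slope exactly equal to the phase rate at the
anchors — the statistic, not the latent parameter, is what the pipeline can
recover.

What the generator does *not* emulate: temperature dependence of growth,
hatching phenology, mortality, size-dependent molt increments (Dyar-rule
drift), or any mechanism of photoperiod perception. Passing recovery tests
therefore show that the pipeline correctly extracts what this design can
express, not that the biological model is complete.

Reproducibility: each generator call seeds R's RNG once from its `seed`
argument; identical seeds give bit-identical datasets. (Per-individual
derived substreams were considered and dropped: a single stream already
guarantees reproducibility, and the generator is vectorised per cohort
rather than per individual.)

## Calibration and recovery checks

Two simulation-based checks accompany the unit tests, with problem sizes
chosen to keep a full run of the suite within a few minutes:

* **Type-I calibration** (`calibrate_null()`): 600 replicates of a null
  configuration — all cell means equal, zero sub-population and family
  variance, 2 replicates per family — fitting the summer/fall model and the
  hatchling ANOVA each time. All four rejection rates (region, photoperiod,
  interaction, hatchling) are required to lie in [0.03, 0.07] at α = 0.05.
* **Pattern recovery**: 25 replicates of the full 330-larva design under the
  default effect sizes, requiring the summer/fall region ordering, the
  overall northern-photoperiod advantage, and the spring crossing
  interaction each in ≥ 80% of replicates, and the truth cell means covered
  by fitted 2-SE intervals in ≥ 90% of cells.

## Known limitations

* Wald chi-square tests are asymptotic; with 8 sub-populations the
  between-population region test is approximate, and calibration was
  verified under zero cluster variance, not under strong clustering.
* The all-night-twilight rule is a modelling decision; chamber almanacs
  rounded to whole minutes may differ from the computed values by a few
  minutes, which is why ±10 minutes is treated as agreement.
* The likely size-mediated correlation between summer/fall and spring rates
  is exposed (both rates plus day-84 size are reported) but not corrected
  for.
* Published test statistics from any particular dataset are not
  reproducible targets; the package's claims are calibration and recovery
  properties under its own generator.
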