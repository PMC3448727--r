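# larvaclock

Photoperiod schedules and seasonal growth-rate analysis for common-garden
larval experiments across latitudes.

Temperate insects read day length as a seasonal clock. To ask whether
populations from different latitudes differ in intrinsic growth rate — and
in how growth responds to the photoperiodic cue — larvae are reared under
chamber photoperiods mimicking chosen latitudes, through an artificial
winter, and measured a few times per individual. `larvaclock` provides the
quantitative machinery for such experiments, for ecologists and
experimentalists designing or analysing them:

* **Photoperiod engine** — light-phase durations for any latitude and date:
  daylight (sun above −0.833°) plus a configurable fraction (default half)
  of each civil twilight (−6° boundary), including the boreal midsummer
  regime where the sun sets but never leaves civil twilight. Full treatment
  schedules with weekly chamber updates, a 14-day winter blackout and a
  spring date-jump (`light_phase()`, `experiment_schedule()`,
  `weekly_schedule()`, `to_hmm()`).
* **Growth-trajectory statistic** — per individual, a cubic on log head
  width over winter-excluded age,
  `L(t) = b0 + b1 t + b2 t^2 + b3 t^3`,
  interpolating the four measurement events; seasonal growth rates are the
  slopes `b1 + 2 b2 t + 3 b3 t^2` at day 21 (mid summer/fall) and day 105
  (mid spring) (`fit_log_cubic()`, `slope_at()`, `seasonal_rates()`).
* **Inferential models** — mixed-effects ANOVAs (via `nlme`) with random
  intercepts for sub-population and family-within-sub-population, Type II
  Wald χ² tests per fixed term (via `car`), covariate screening, a one-way
  hatchling ANOVA, an adult-size model with a sex contrast, and hatch-size /
  growth regressions (`fit_seasonal_model()`, `hatchling_anova()`,
  `adult_size_model()`, `hatch_growth_regression()`).
* **Molt-based simulator** — the full hierarchical design (3 regions, 3/4/1
  sub-populations, 14/14/5 families, clutches split across two photoperiod
  treatments, 5 replicates each; 165 larvae per treatment) with growth as a
  rate-matched Poisson molt process, plus hatchling and field-adult tables
  and a truth record for recovery checks (`simulate_experiment()`,
  `sim_config()`).
* **Pipeline** — simulate or load CSV tables, fit everything, and produce a
  report with cell means and 95% CIs, model term tables, variance
  components and a run log (`run_pipeline()`, `summarize_cells()`,
  `calibrate_null()`).

## Worked example

```r
library(larvaclock)

# What should a chamber mimicking 64N be set to on 10 July 2010?
lp <- light_phase(64, as.Date("2010-07-10"))
lp
#>   latitude       date light_hours dark_hours             regime
#> 1       64 2010-07-10    22.07977   1.920232 all_night_twilight
to_hmm(lp$light_hours)   # hours.minutes notation
#> [1] 22.05
```

22 h 05 min of light: actual daylight is only ~20.2 h, but at 64°N in July
the sun never drops below −6°, so the whole night is civil twilight and half
of it counts as light.

```r
report <- run_pipeline("simulate", seed = 1)
report
```

```
Growth-rate analysis report (seed 1)
 individuals analysed: 330  excluded: 0

Mixed-effects ANOVA (Wald chi-square), response: summer_fall
  n = 330  random structure: nested
               term  chisq df        p
             region  0.257  2 8.79e-01
        photoperiod 56.651  1 5.20e-14
      hatch_size_mm  6.954  1 8.36e-03
 region:photoperiod  8.082  2 1.76e-02
  covariate hatch_size_mm : keep (p = 0.00836 )

Mixed-effects ANOVA (Wald chi-square), response: spring
  n = 330  random structure: nested
               term  chisq df        p
             region  4.201  2 1.22e-01
        photoperiod  1.987  1 1.59e-01
      size_day84_mm  5.899  1 1.52e-02
 region:photoperiod 20.121  2 4.27e-05
  covariate size_day84_mm : keep (p = 0.0152 )

Hatchling one-way ANOVA: F(2,327) = 86.41, p = 7.45e-31

Mixed-effects ANOVA (Wald chi-square), response: adult size
  n = 287  random structure: population
       term chisq df     p
     region 0.259  2 0.878
        sex 0.829  1 0.363
 region:sex 2.387  2 0.303

hatch-size regression (summer_fall): slope = -0.139, r^2 = 0.128, p = 2.28e-06
hatch-size regression (spring): slope = 0.0641, r^2 = 0.038, p = 0.0117
```

Reading this: the simulated experiment shows a strong summer/fall
photoperiod effect (larvae grow faster under the northern photoperiod) and a
region × photoperiod interaction in spring — the crossing pattern in which
the central region grows faster under the *southern* photoperiod while the
high-latitude regions do the opposite (see `report$cells` for the cell
means). Hatchling size differs sharply between regions and is negatively
related to summer/fall growth. Because the simulated hatch-size cline is
confounded with region, the screened hatch-size covariate is retained here
and absorbs much of the region main effect — the usual covariate caveat,
discussed in the methods vignette. Field adults show no region effect, by
design.

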