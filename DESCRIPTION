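Package: larvaclock
Title: Photoperiod Schedules and Seasonal Growth-Rate Analysis for
    Common-Garden Larval Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing common-garden experiments on
    photoperiodic regulation of larval growth across latitudes. Computes
    light-phase durations (daylight plus a configurable fraction of civil
    twilight) for any latitude and date, generates rearing-chamber treatment
    schedules with a winter blackout and a spring date-jump, fits
    per-individual cubic growth trajectories on log head width over a
    winter-excluded age axis, extracts summer/fall and spring growth rates as
    slopes at fixed ages, and fits the corresponding nested mixed-effects
    ANOVAs (Wald chi-square tests) together with hatchling-size and adult-size
    analyses. A molt-based stochastic simulator generates datasets with the
    full hierarchical design (regions, sub-populations, families, split
    clutches across two photoperiod treatments) so every pipeline stage can be
    exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    car,
    stats,
    utils
Suggests:
    lme4,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
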