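#' Simulation configuration for the common-garden design
#'
#' Bundles every design count, effect size and variance component the
#' generator needs. Defaults mirror the full experimental design: three
#' latitudinal regions (central 62N: 3 sub-populations with 6/4/4 families;
#' northern 65.5N: 4 sub-populations with 5/3/3/3 families; northernmost
#' 66.5N: 1 sub-population with 5 families), egg clutches split between two
#' photoperiod treatments (southern 52N, northern 64N), 5 larval replicates
#' per family per treatment (165 larvae per treatment), four measurement
#' events at 42-day intervals on a winter-excluded age axis, and a 14-day
#' winter with no growth.
#'
#' Growth-rate cell means (log-mm/day) default to a pattern qualitatively
#' matching the study system: in summer/fall, rates decrease with latitude of
#' origin and are higher under the northern photoperiod, with the photoperiod
#' gap largest in the central region and negligible in the northernmost; in
#' spring the central region grows faster under the southern photoperiod
#' while the two high-latitude regions keep the northern-photoperiod
#' advantage (a crossing interaction). Hatchling head width increases with
#' latitude of origin. Field adults default to equal region means with a
#' +0.06 mm male offset.
#'
#' @param replicates larvae per family per treatment (default 5).
#' @param subpop_families named list: families per sub-population, per region.
#' @param latitudes region latitudes (degrees N), for metadata.
#' @param ages measurement ages, winter-excluded days (default 0,42,84,126).
#' @param winter_days winter length excluded from the age axis (default 14).
#' @param winter_start_age winter-excluded age at which winter falls and the
#'   seasonal rate regime switches (default 63).
#' @param fall_rates,spring_rates 3 x 2 matrices of mean log growth rates
#'   (rows: central, northern, northernmost; cols: southern, northern
#'   photoperiod), log-mm/day.
#' @param sd_pop,sd_fam,sd_resid standard deviations of the sub-population,
#'   family and individual deviations added to each phase's mean rate
#'   (log-mm/day).
#' @param hatch_means mean hatchling head width per region (mm).
#' @param hatch_sd_family,hatch_sd between-family and within-family SD of
#'   hatchling head width (mm).
#' @param n_hatchlings hatchlings measured per family (default 10).
#' @param molt_ratio head-width multiplier per molt (default 1.25).
#' @param meas_sd lognormal measurement-error SD on the log scale.
#' @param adult list: `region_means` (mm), `sex_offset` (male - female, mm),
#'   `sd_pop`, `sd_resid`, and `sites` (per-site male/female sample sizes;
#'   defaults to the field collection: central 20/20 at each of 3 sites,
#'   northern males 15/17/20/20 and females 6/9/17/19, northernmost males
#'   17/13 and females 7/7).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(replicates = 5,
                       subpop_families = list(central = c(6, 4, 4),
                                              northern = c(5, 3, 3, 3),
                                              northernmost = c(5)),
                       latitudes = c(central = 62, northern = 65.5,
                                     northernmost = 66.5),
                       ages = c(0, 42, 84, 126),
                       winter_days = 14,
                       winter_start_age = 63,
                       fall_rates = rbind(central = c(0.010, 0.020),
                                          northern = c(0.009, 0.014),
                                          northernmost = c(0.008, 0.009)),
                       spring_rates = rbind(central = c(0.014, 0.008),
                                            northern = c(0.008, 0.013),
                                            northernmost = c(0.0085, 0.013)),
                       sd_pop = 5e-4, sd_fam = 1e-3, sd_resid = 2e-3,
                       hatch_means = c(central = 0.44, northern = 0.47,
                                       northernmost = 0.50),
                       hatch_sd_family = 0.015, hatch_sd = 0.03,
                       n_hatchlings = 10,
                       molt_ratio = 1.25, meas_sd = 0.01,
                       adult = list()) {
  regions <- names(subpop_families)
  colnames(fall_rates) <- colnames(spring_rates) <- c("southern", "northern")
  adult_default <- list(
    region_means = setNames(rep(3.5, length(regions)), regions),
    sex_offset = 0.06, sd_pop = 0.02, sd_resid = 0.25,
    sites = data.frame(
      region = c(rep("central", 3), rep("northern", 4),
                 rep("northernmost", 2)),
      site = c(paste0("AC", 1:3), paste0("AN", 1:4), paste0("AM", 1:2)),
      n_male = c(20, 20, 20, 15, 17, 20, 20, 17, 13),
      n_female = c(20, 20, 20, 6, 9, 17, 19, 7, 7),
      stringsAsFactors = FALSE))
  adult <- utils::modifyList(adult_default, adult)
  cfg <- list(replicates = replicates, subpop_families = subpop_families,
              latitudes = latitudes, ages = ages, winter_days = winter_days,
              winter_start_age = winter_start_age,
              fall_rates = fall_rates, spring_rates = spring_rates,
              sd_pop = sd_pop, sd_fam = sd_fam, sd_resid = sd_resid,
              hatch_means = hatch_means, hatch_sd_family = hatch_sd_family,
              hatch_sd = hatch_sd, n_hatchlings = n_hatchlings,
              molt_ratio = molt_ratio, meas_sd = meas_sd, adult = adult)
  stopifnot(replicates > 0, molt_ratio > 1, meas_sd >= 0,
            sd_pop >= 0, sd_fam >= 0, sd_resid >= 0,
            all(diff(ages) > 0), length(regions) == length(hatch_means),
            nrow(fall_rates) == length(regions))
  structure(cfg, class = "sim_config")
}

#' Null-effect configuration for calibration runs
#'
#' All region x photoperiod growth-rate cell means equal, sub-population and
#' family variance components zero, equal hatchling region means and zero
#' adult region/sex effects: the configuration under which every fixed-effect
#' test holds its nominal type-I error. `replicates` defaults to 2 so
#' replicated calibration runs stay cheap.
#'
#' @param replicates larvae per family per treatment (default 2).
#' @param rate common growth-rate mean for all cells (default 0.01).
#' @param ... further overrides passed to [sim_config()].
#' @return A `"sim_config"` object.
#' @export
sim_config_null <- function(replicates = 2, rate = 0.01, ...) {
  flat <- matrix(rate, 3, 2)
  rownames(flat) <- c("central", "northern", "northernmost")
  sim_config(replicates = replicates,
             fall_rates = flat, spring_rates = flat,
             sd_pop = 0, sd_fam = 0, sd_resid = 0,
             hatch_means = c(central = 0.47, northern = 0.47,
                             northernmost = 0.47),
             hatch_sd_family = 0,
             adult = list(sex_offset = 0, sd_pop = 0),
             ...)
}

#' Simulate one individual's molt-based growth trajectory
#'
#' Insects grow in steps: head width is constant within an instar and
#' multiplies by the molt increment ratio `r` at each molt. Molts arrive as a
#' Poisson process (exponential intermolt times) whose rate is matched to the
#' target expected log growth rate, `rate / log(r)` molts per day, switching
#' from the summer/fall to the spring rate at `phase_change_age` (the ages
#' are winter-excluded, so the winter pause contributes no molts by
#' construction). Observed widths carry multiplicative lognormal measurement
#' error.
#'
#' @param rate_fall,rate_spring expected log growth rates (log-mm/day);
#'   non-positive rates give a molt-free phase.
#' @param hatch_width true head width at hatching, mm.
#' @param ages measurement ages (winter-excluded days).
#' @param molt_ratio head-width multiplier per molt.
#' @param meas_sd measurement-error SD on the log scale.
#' @param phase_change_age age at which the rate regime switches (days).
#' @param observed_day0 optional value recorded at age 0 instead of the
#'   individual's own measured width (the family-mean hatchling estimate, as
#'   in the experimental protocol).
#' @return A list with `observed` (widths at `ages`), `true_widths` (step
#'   values at `ages`), `molt_ages` and `width_at` (step function of age).
#' @export
simulate_individual <- function(rate_fall, rate_spring, hatch_width,
                                ages = c(0, 42, 84, 126), molt_ratio = 1.25,
                                meas_sd = 0.01, phase_change_age = 63,
                                observed_day0 = NULL) {
  stopifnot(is.finite(rate_fall), is.finite(rate_spring), hatch_width > 0)
  logr <- log(molt_ratio)
  horizon <- max(ages)
  draw_phase <- function(lambda, t0, t1) {
    if (lambda <= 0 || t1 <= t0) return(numeric(0))
    t <- t0; out <- numeric(0)
    repeat {
      t <- t + rexp(1, lambda)
      if (t > t1) break
      out <- c(out, t)
    }
    out
  }
  molts <- c(draw_phase(max(rate_fall, 0) / logr, 0,
                        min(phase_change_age, horizon)),
             draw_phase(max(rate_spring, 0) / logr,
                        min(phase_change_age, horizon), horizon))
  width_at <- function(age) {
    hatch_width * molt_ratio^vapply(age, function(a) sum(molts <= a),
                                    numeric(1))
  }
  true_w <- width_at(ages)
  obs <- true_w * exp(rnorm(length(ages), 0, meas_sd))
  if (!is.null(observed_day0) && any(ages == 0))
    obs[ages == 0] <- observed_day0
  list(observed = obs, true_widths = true_w, molt_ages = molts,
       width_at = width_at)
}

# Design table: one row per family with region, sub-population and latent
# effects; shared across both treatments (clutch halves).
build_design <- function(config) {
  rows <- list()
  for (region in names(config$subpop_families)) {
    fams <- config$subpop_families[[region]]
    for (s in seq_along(fams)) {
      pop <- sprintf("%s_P%d", region, s)
      for (f in seq_len(fams[s])) {
        rows[[length(rows) + 1]] <- data.frame(
          region = region, sub_population = pop,
          family = sprintf("%s_F%d", pop, f), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate hatchling-size records
#'
#' `n_hatchlings` hatchlings per family, from the northern-photoperiod batch
#' (the only one in which hatchlings are measured). Family means are region
#' mean + a family deviation; individual hatchlings add within-family noise.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return A data.frame `family`, `region`, `head_width_mm` with the latent
#'   family means in attribute `"family_means"`.
#' @export
simulate_hatchlings <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- build_design(config)
  fam_mean <- config$hatch_means[design$region] +
    rnorm(nrow(design), 0, config$hatch_sd_family)
  out <- data.frame(
    family = rep(design$family, each = config$n_hatchlings),
    region = rep(design$region, each = config$n_hatchlings),
    head_width_mm = rnorm(nrow(design) * config$n_hatchlings,
                          rep(fam_mean, each = config$n_hatchlings),
                          config$hatch_sd),
    stringsAsFactors = FALSE)
  attr(out, "family_means") <- setNames(fam_mean, design$family)
  out
}

#' Simulate field-collected adult records
#'
#' Head width = region mean + population deviation + sex offset (applied
#' half-and-half so the male - female difference equals `sex_offset`) +
#' residual noise, with per-site male/female counts from the configuration.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return A data.frame `region`, `population`, `sex`, `head_width_mm`.
#' @export
simulate_adults <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ad <- config$adult
  sites <- ad$sites
  pop_dev <- rnorm(nrow(sites), 0, ad$sd_pop)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    n <- c(male = sites$n_male[i], female = sites$n_female[i])
    sex <- rep(names(n), n)
    mu <- ad$region_means[[sites$region[i]]] + pop_dev[i] +
      ifelse(sex == "male", ad$sex_offset / 2, -ad$sex_offset / 2)
    data.frame(region = sites$region[i], population = sites$site[i],
               sex = sex, head_width_mm = rnorm(sum(n), mu, ad$sd_resid),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a full common-garden experiment
#'
#' Generates the three analysis tables (larval measurements, hatchlings,
#' field adults) plus a truth record of all latent effects. Each family's
#' clutch is split across both photoperiod treatments, sharing its family
#' (and sub-population) rate deviations; each individual's expected log
#' growth rate in each phase is the region x treatment cell mean plus those
#' deviations plus an individual residual. Widths follow the molt process of
#' [simulate_individual()] (vectorised as Poisson molt-count increments
#' between measurement ages). The value recorded at age 0 is the family-mean
#' hatchling size, as in the laboratory protocol. The truth table stores, per
#' individual, the latent phase rates and the expected anchor-day slopes
#' implied by fitting the cubic to the expected log trajectory -- the
#' estimand the downstream pipeline should recover.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default 1); identical seeds give bit-identical
#'   datasets.
#' @param anchors a [season_anchors()] used for the truth-table expected
#'   slopes.
#' @return An object of class `"synthetic_dataset"`: list with
#'   `measurements`, `hatchlings`, `adults`, `truth` and `config`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1,
                                anchors = season_anchors()) {
  set.seed(seed)
  design <- build_design(config)
  hatch <- simulate_hatchlings(config, seed = NULL)
  fam_hatch_est <- tapply(hatch$head_width_mm, hatch$family, mean)

  pops <- unique(design$sub_population)
  pop_dev_fall <- setNames(rnorm(length(pops), 0, config$sd_pop), pops)
  pop_dev_spring <- setNames(rnorm(length(pops), 0, config$sd_pop), pops)
  fam_dev_fall <- setNames(rnorm(nrow(design), 0, config$sd_fam),
                           design$family)
  fam_dev_spring <- setNames(rnorm(nrow(design), 0, config$sd_fam),
                             design$family)

  treatments <- c("southern", "northern")
  ind <- do.call(rbind, lapply(treatments, function(tr) {
    d <- design[rep(seq_len(nrow(design)), each = config$replicates), ]
    d$photoperiod <- tr
    d$replicate <- rep(seq_len(config$replicates), nrow(design))
    d
  }))
  ind$individual_id <- sprintf("%s_%s_R%d", ind$family,
                               substr(ind$photoperiod, 1, 1), ind$replicate)
  ind$rate_fall <- config$fall_rates[cbind(ind$region, ind$photoperiod)] +
    pop_dev_fall[ind$sub_population] + fam_dev_fall[ind$family] +
    rnorm(nrow(ind), 0, config$sd_resid)
  ind$rate_spring <- config$spring_rates[cbind(ind$region, ind$photoperiod)] +
    pop_dev_spring[ind$sub_population] + fam_dev_spring[ind$family] +
    rnorm(nrow(ind), 0, config$sd_resid)
  fam_means <- attr(hatch, "family_means")
  ind$hatch_width <- pmax(fam_means[ind$family] +
                            rnorm(nrow(ind), 0, config$hatch_sd), 0.05)

  # Poisson molt-count increments between measurement ages, per phase
  ages <- config$ages
  logr <- log(config$molt_ratio)
  pca <- config$winter_start_age
  n_ind <- nrow(ind)
  molt_counts <- matrix(0L, n_ind, length(ages))
  for (j in seq_along(ages)[-1]) {
    t0 <- ages[j - 1]; t1 <- ages[j]
    fall_time <- max(0, min(t1, pca) - min(t0, pca))
    spring_time <- max(0, t1 - max(t0, pca))
    lam <- (pmax(ind$rate_fall, 0) * fall_time +
              pmax(ind$rate_spring, 0) * spring_time) / logr
    molt_counts[, j] <- molt_counts[, j - 1] + rpois(n_ind, lam)
  }
  true_w <- ind$hatch_width * config$molt_ratio^molt_counts
  obs_w <- true_w * exp(matrix(rnorm(n_ind * length(ages), 0,
                                     config$meas_sd), n_ind))
  if (any(ages == 0))
    obs_w[, ages == 0] <- fam_hatch_est[ind$family]

  measurements <- data.frame(
    individual_id = rep(ind$individual_id, each = length(ages)),
    family = rep(ind$family, each = length(ages)),
    sub_population = rep(ind$sub_population, each = length(ages)),
    region = rep(ind$region, each = length(ages)),
    photoperiod = rep(ind$photoperiod, each = length(ages)),
    event_index = rep(seq_along(ages), n_ind),
    age_days = rep(ages, n_ind),
    head_width_mm = as.vector(t(obs_w)),
    stringsAsFactors = FALSE)

  # expected anchor slopes: cubic through the expected log trajectory
  exp_slopes <- t(vapply(seq_len(n_ind), function(i) {
    Lexp <- log(ind$hatch_width[i]) +
      pmax(ind$rate_fall[i], 0) * pmin(ages, pca) +
      pmax(ind$rate_spring[i], 0) * pmax(ages - pca, 0)
    fit <- fit_log_cubic(ages, exp(Lexp))
    c(slope_at(fit, anchors$summer_fall_day),
      slope_at(fit, anchors$spring_day))
  }, numeric(2)))
  truth <- data.frame(ind[c("individual_id", "family", "sub_population",
                            "region", "photoperiod", "rate_fall",
                            "rate_spring", "hatch_width")],
                      expected_fall_slope = exp_slopes[, 1],
                      expected_spring_slope = exp_slopes[, 2],
                      stringsAsFactors = FALSE)

  adults <- simulate_adults(config, seed = NULL)
  structure(list(measurements = measurements, hatchlings = hatch,
                 adults = adults, truth = truth, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic common-garden dataset\n")
  cat("  individuals:", nrow(x$truth), "(",
      paste(table(x$truth$photoperiod), collapse = " + "),
      "per photoperiod )\n")
  cat("  measurement rows:", nrow(x$measurements),
      " hatchlings:", nrow(x$hatchlings),
      " adults:", nrow(x$adults), "\n")
  invisible(x)
}
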