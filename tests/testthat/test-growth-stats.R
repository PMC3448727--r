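test_that("a pure photoperiod shift with no noise separates deterministically", {
  rec <- make_rate_records(n_per_cell = 8, photo_shift = 0.005, sigma = 0)
  fit <- suppressWarnings(
    fit_seasonal_model(rec, "summer_fall", covariate = "none"))
  tab <- fit$anova
  expect_lt(tab$p[tab$term == "photoperiod"], 1e-10)
  expect_gt(tab$p[tab$term == "region"], 0.99)
  expect_gt(tab$p[tab$term == "region:photoperiod"], 0.99)
  expect_false(fit$converged)  # zero residual variance forces the fallback
})

test_that("Wald chi-square for a 2-level factor equals (estimate/SE)^2", {
  rec <- make_rate_records(n_per_cell = 12, photo_shift = 0.002, seed = 8)
  fit <- fit_seasonal_model(rec, "summer_fall", covariate = "none",
                            interaction = FALSE)
  est <- fit$fixed[grepl("^photoperiod", fit$fixed$term), ]
  chisq <- fit$anova$chisq[fit$anova$term == "photoperiod"]
  expect_equal(chisq, (est$estimate / est$se)^2, tolerance = 1e-6)
})

test_that("mixed fit matches lme4 and a fixed-effects ANOVA where it should", {
  skip_if_not_installed("lme4")
  ds <- simulate_experiment(sim_config(), seed = 11)
  rec <- seasonal_rates(ds$measurements, hatchlings = ds$hatchlings)
  fit <- fit_seasonal_model(rec, "summer_fall", covariate = "none")
  lf <- lme4::lmer(
    summer_fall_rate ~ region * photoperiod + (1 | sub_population / family),
    data = rec, REML = TRUE)
  expect_equal(fit$fixed$estimate, unname(lme4::fixef(lf)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$varcomp$variance[fit$varcomp$component == "residual"],
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
  # degenerate limit: no hierarchical variance -> same conclusions as aov
  rec0 <- make_rate_records(n_per_cell = 10, photo_shift = 0.003,
                            region_shift = c(0, 0.002, 0.004), seed = 5)
  mf <- fit_seasonal_model(rec0, "summer_fall", covariate = "none")
  av <- anova(lm(summer_fall_rate ~ region * photoperiod, data = rec0))
  p_aov <- setNames(av[["Pr(>F)"]][1:3],
                    c("region", "photoperiod", "region:photoperiod"))
  for (tm in names(p_aov)) {
    p_mixed <- mf$anova$p[mf$anova$term == tm]
    expect_equal(p_mixed < 0.05, p_aov[[tm]] < 0.05)
    # chi-square vs F reference distributions differ slightly at this n
    expect_lt(abs(p_mixed - p_aov[[tm]]), 0.06)
  }
})

test_that("interaction Wald p agrees with a permutation test on balanced data", {
  rec <- make_rate_records(n_per_cell = 8, photo_shift = 0, sigma = 0.002,
                           seed = 21)
  fit <- fit_seasonal_model(rec, "summer_fall", covariate = "none")
  p_wald <- fit$anova$p[fit$anova$term == "region:photoperiod"]
  # permutation reference: RSS drop of the interaction under full shuffling
  X_full <- stats::model.matrix(~ region * photoperiod, rec)
  X_red <- stats::model.matrix(~ region + photoperiod, rec)
  rss <- function(X, y) sum(stats::lm.fit(X, y)$residuals^2)
  y <- rec$summer_fall_rate
  stat <- function(y) rss(X_red, y) - rss(X_full, y)
  obs <- stat(y)
  set.seed(99)
  perm <- replicate(2000, stat(sample(y)))
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_wald - p_perm), 0.05)
})

test_that("covariate screening keeps signal and drops noise or constants", {
  rec <- make_rate_records(n_per_cell = 10, seed = 13)
  # covariate equal to the response: kept, p ~ 0
  rec$hatch_size_mm <- rec$summer_fall_rate
  keep <- suppressWarnings(screen_covariate(rec, "summer_fall"))
  expect_equal(keep$decision, "keep")
  expect_lt(keep$p, 1e-10)
  # constant covariate: inestimable, dropped
  rec$hatch_size_mm <- 0.45
  expect_equal(screen_covariate(rec, "summer_fall")$decision, "drop")
  # all-missing covariate: dropped with a warning
  rec$hatch_size_mm <- NA_real_
  expect_warning(out <- screen_covariate(rec, "summer_fall"), "unavailable")
  expect_equal(out$decision, "drop")
  # pure-noise covariate: dropped in most null replicates
  kept <- 0
  for (s in 1:20) {
    r <- make_rate_records(n_per_cell = 6, seed = 100 + s)
    if (screen_covariate(r, "summer_fall")$decision == "keep") kept <- kept + 1
  }
  expect_lte(kept / 20, 0.25)
})

test_that("one-way hatchling ANOVA matches hand-computed sums of squares", {
  h <- data.frame(region = rep(c("central", "northern", "northernmost"),
                               each = 5),
                  head_width_mm = c(0.42, 0.44, 0.43, 0.45, 0.41,
                                    0.47, 0.46, 0.48, 0.45, 0.49,
                                    0.50, 0.52, 0.49, 0.51, 0.53))
  out <- hatchling_anova(h)
  # textbook one-way SS computed directly
  g <- split(h$head_width_mm, h$region)
  grand <- mean(h$head_width_mm)
  ss_b <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2, 1))
  ss_w <- sum(vapply(g, function(x) sum((x - mean(x))^2), 1))
  F_hand <- (ss_b / 2) / (ss_w / 12)
  expect_equal(out$F, F_hand, tolerance = 1e-10)
  expect_equal(out$df1, 2)
  expect_equal(out$df2, 12)
  expect_equal(out$p, stats::pf(F_hand, 2, 12, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("degenerate hatchling inputs resolve deterministically", {
  same_within <- data.frame(region = rep(c("a", "b", "c"), each = 3),
                            head_width_mm = rep(c(0.4, 0.5, 0.6), each = 3))
  out <- hatchling_anova(same_within)
  expect_equal(out$F, Inf)
  expect_equal(out$p, 0)
  flat <- data.frame(region = rep(c("a", "b"), each = 3),
                     head_width_mm = rep(0.5, 6))
  out <- hatchling_anova(flat)
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)
  lonely <- rbind(same_within,
                  data.frame(region = "d", head_width_mm = 0.7))
  expect_warning(out <- hatchling_anova(lonely), "excluding")
  expect_equal(out$n, 9)
})

test_that("adult model isolates the sex contrast and degenerates to two-way ANOVA", {
  # noise-free adults: the male - female contrast is recovered exactly
  ad <- expand.grid(population = paste0("P", 1:6), sex = c("female", "male"),
                    rep = 1:5, stringsAsFactors = FALSE)
  ad$region <- rep(c("central", "northern", "northernmost"), each = 2)[
    match(ad$population, paste0("P", 1:6))]
  ad$head_width_mm <- 3.5 + 0.06 * (ad$sex == "male")
  fit <- suppressWarnings(adult_size_model(ad))
  expect_equal(unname(fit$sex_contrast["estimate"]), 0.06, tolerance = 1e-8)
  # identical sexes: sex chi-square ~ 0
  ad$head_width_mm <- 3.5 + rep_len(c(-0.01, 0.01), nrow(ad))
  ad$head_width_mm <- ave(ad$head_width_mm, ad$population)  # sex-symmetric
  fit2 <- suppressWarnings(adult_size_model(ad))
  expect_lt(fit2$anova$chisq[fit2$anova$term == "sex"], 1e-6)
  # one population per region, no population variance: matches fixed ANOVA
  set.seed(31)
  ad3 <- expand.grid(population = c("p1", "p2", "p3"),
                     sex = c("female", "male"), rep = 1:12,
                     stringsAsFactors = FALSE)
  ad3$region <- sub("p", "r", ad3$population)
  ad3$head_width_mm <- rnorm(nrow(ad3), 3.5 + 0.05 * (ad3$sex == "male"), 0.2)
  fit3 <- adult_size_model(ad3)
  av <- anova(lm(head_width_mm ~ region * sex, data = ad3))
  expect_equal(fit3$anova$p[fit3$anova$term == "sex"],
               av[["Pr(>F)"]][2], tolerance = 0.02)
})

test_that("adult model has power for the reported sex effect at the field n", {
  # study-sized samples with SE(contrast) ~ 0.03: detection is well above
  # the 5% type-I level and the estimate is unbiased
  p <- numeric(60); est <- numeric(60)
  for (s in seq_along(p)) {
    ad <- simulate_adults(sim_config(), seed = 500 + s)
    fit <- adult_size_model(ad)
    p[s] <- fit$anova$p[fit$anova$term == "sex"]
    est[s] <- fit$sex_contrast["estimate"]
  }
  expect_lt(abs(mean(est) - 0.06), 0.015)
  expect_gt(mean(p < 0.05), 0.25)
})

test_that("hatch-size regression recovers exact and null relationships", {
  rec <- make_rate_records(n_per_cell = 10, seed = 17)
  rec$hatch_size_mm <- runif(nrow(rec), 0.4, 0.5)
  rec$summer_fall_rate <- 0.02 - 0.02 * rec$hatch_size_mm
  out <- suppressWarnings(hatch_growth_regression(rec, "summer_fall"))
  expect_equal(out$r_squared, 1, tolerance = 1e-9)
  expect_equal(out$slope, -0.02, tolerance = 1e-9)
  expect_equal(out$sign, -1)
  expect_equal(out$n, sum(rec$photoperiod == "northern"))
  # family aggregation mode
  agg <- suppressWarnings(
    hatch_growth_regression(rec, "summer_fall", aggregate_families = TRUE))
  expect_equal(agg$slope, -0.02, tolerance = 1e-6)
  expect_error(hatch_growth_regression(rec[1:2, ], "summer_fall"),
               "at least 3")
})
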