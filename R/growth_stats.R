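#' @importFrom stats coef complete.cases lm anova qnorm reformulate sd
#'   setNames vcov rnorm rexp rpois
NULL

rate_column <- function(season) {
  switch(match.arg(season, c("summer_fall", "spring")),
         summer_fall = "summer_fall_rate", spring = "spring_rate")
}

covariate_for <- function(season) {
  switch(season, summer_fall = "hatch_size_mm", spring = "size_day84_mm")
}

# Fit lme with a convergence/singularity fallback cascade:
# full nesting -> population only -> fixed-effects lm. Returns the fit, the
# random structure actually used and a convergence flag.
fit_lme_cascade <- function(fixed, data, random_terms, method) {
  notes <- character(0)
  controls <- list(default = nlme::lmeControl(),
                   optim = nlme::lmeControl(opt = "optim", maxIter = 200,
                                            msMaxIter = 200))
  y <- stats::model.response(stats::model.frame(fixed, data))
  for (i in seq_along(random_terms)) {
    for (ctl in names(controls)) {
      fit <- tryCatch(
        nlme::lme(fixed, random = random_terms[[i]], data = data,
                  method = method, control = controls[[ctl]]),
        error = function(e) e)
      if (!inherits(fit, "error")) {
        # an essentially zero residual variance makes Wald tests meaningless;
        # treat as singular and keep falling through
        if (fit$sigma^2 > 1e-10 * max(stats::var(y), 1e-300))
          return(list(fit = fit, converged = i == 1L, notes = notes,
                      random_used = names(random_terms)[i]))
        notes <- c(notes, paste0("lme(", names(random_terms)[i], ", ", ctl,
                                 ") degenerate: residual variance ~ 0"))
      } else {
        notes <- c(notes, paste0("lme(", names(random_terms)[i], ", ", ctl,
                                 ") failed: ", conditionMessage(fit)))
      }
    }
  }
  fit <- lm(fixed, data = data)
  list(fit = fit, converged = FALSE, notes = notes, random_used = "none")
}

# Wald chi-square table via car::Anova for lme fits; for the lm fallback the
# F table is converted to chi-square = df * F (the same Wald statistic).
wald_table <- function(fit, type = "II") {
  if (inherits(fit, "lme")) {
    a <- car::Anova(fit, type = type)
    data.frame(term = rownames(a), chisq = a[["Chisq"]], df = a[["Df"]],
               p = a[["Pr(>Chisq)"]], row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    a <- tryCatch(car::Anova(fit, type = type), error = function(e) NULL)
    if (!is.null(a)) {
      keep <- rownames(a) != "Residuals"
      df <- a[["Df"]][keep]
      chisq <- df * a[["F value"]][keep]
      return(data.frame(term = rownames(a)[keep], chisq = chisq, df = df,
                        p = stats::pchisq(chisq, df, lower.tail = FALSE),
                        row.names = NULL, stringsAsFactors = FALSE))
    }
    # car::Anova refuses (near-)perfect fits; resolve them from Type II sums
    # of squares: a non-zero term sum of squares against a zero residual is
    # infinitely strong evidence, a zero one is none at all
    X <- stats::model.matrix(fit)
    asgn <- attr(X, "assign")
    y <- stats::model.response(stats::model.frame(fit))
    tl <- attr(stats::terms(fit), "term.labels")
    varlist <- lapply(tl, function(t) strsplit(t, ":")[[1]])
    rss <- function(cols) {
      if (!any(cols)) return(sum((y - mean(y))^2))
      sum(stats::lm.fit(X[, cols, drop = FALSE], y)$residuals^2)
    }
    tot <- max(sum((y - mean(y))^2), 1e-300)
    ss2 <- vapply(seq_along(tl), function(i) {
      contains <- vapply(seq_along(tl), function(j)
        i != j && all(varlist[[i]] %in% varlist[[j]]), logical(1))
      base_terms <- setdiff(seq_along(tl), c(i, which(contains)))
      rss(asgn %in% c(0, base_terms)) - rss(asgn %in% c(0, base_terms, i))
    }, numeric(1))
    df <- vapply(seq_along(tl), function(i) sum(asgn == i), numeric(1))
    chisq <- ifelse(ss2 > 1e-12 * tot, Inf, 0)
    data.frame(term = tl, chisq = chisq, df = df,
               p = stats::pchisq(chisq, df, lower.tail = FALSE),
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

variance_components <- function(fit) {
  if (!inherits(fit, "lme")) {
    return(data.frame(component = "residual",
                      variance = summary(fit)$sigma^2,
                      stringsAsFactors = FALSE))
  }
  vc <- nlme::VarCorr(fit)
  v <- suppressWarnings(as.numeric(vc[, "Variance"]))
  vals <- v[!is.na(v)]
  groups <- names(fit$groups)  # outermost first
  data.frame(component = c(groups, "residual"),
             variance = vals[seq_len(length(groups) + 1)],
             stringsAsFactors = FALSE)
}

#' Screen a covariate in the seasonal growth model
#'
#' The covariate (hatchling size for summer/fall, day-84 size for spring) is
#' retained in the final model only if its Wald test in the full mixed model
#' is significant at `alpha`. Rows with a missing covariate are dropped for
#' screening; a covariate with no usable values or no variance is dropped as
#' inestimable.
#'
#' @param records a growth-rate table from [seasonal_rates()].
#' @param season `"summer_fall"` or `"spring"`.
#' @param covariate covariate column name; defaults to the season's
#'   conventional covariate.
#' @param alpha screening level (default 0.05).
#' @param method `"REML"` (default) or `"ML"`.
#' @return A list with `decision` (`"keep"` or `"drop"`), `p`, `covariate`
#'   and `n` (rows used).
#' @export
screen_covariate <- function(records, season = c("summer_fall", "spring"),
                             covariate = NULL, alpha = 0.05,
                             method = "REML") {
  season <- match.arg(season)
  if (is.null(covariate)) covariate <- covariate_for(season)
  resp <- rate_column(season)
  if (!covariate %in% names(records) || all(is.na(records[[covariate]]))) {
    warning("covariate `", covariate, "` unavailable; dropped")
    return(list(decision = "drop", p = NA_real_, covariate = covariate,
                n = 0L))
  }
  d <- records[complete.cases(records[c(resp, covariate)]), ]
  if (length(unique(d[[covariate]])) < 2) {
    return(list(decision = "drop", p = NA_real_, covariate = covariate,
                n = nrow(d)))
  }
  fixed <- reformulate(c("region", "photoperiod", "region:photoperiod",
                         covariate), response = resp)
  fv <- fit_lme_cascade(fixed, d,
                        list(nested = ~ 1 | sub_population / family,
                             population = ~ 1 | sub_population),
                        method)
  tab <- wald_table(fv$fit)
  p <- tab$p[tab$term == covariate]
  list(decision = if (length(p) && is.finite(p) && p < alpha) "keep"
       else "drop",
       p = if (length(p)) p else NA_real_, covariate = covariate,
       n = nrow(d))
}

#' Mixed-effects ANOVA for a seasonal growth rate
#'
#' Fits the growth rate for one season against region of origin, photoperiod
#' treatment and their interaction (fixed), with random intercepts for
#' sub-population and for family nested within sub-population, and reports
#' Type II Wald chi-square tests per fixed term plus variance components.
#' The seasonal covariate is screened first (see [screen_covariate()]) and
#' enters the final model only if significant. Singular or non-converging
#' fits fall back to a simpler random structure (then to a fixed-effects
#' model), flagged in the result.
#'
#' @param records a growth-rate table from [seasonal_rates()].
#' @param season `"summer_fall"` or `"spring"`.
#' @param covariate covariate column, `NULL` for the season default, or
#'   `"none"` to skip screening entirely.
#' @param interaction include the region x photoperiod interaction
#'   (default TRUE).
#' @param screen_alpha screening level for the covariate.
#' @param method `"REML"` (default) or `"ML"`.
#' @param type Wald test type, `"II"` (default) or `"III"`.
#' @return An object of class `"model_fit"`: list with `anova` (term,
#'   chisq, df, p), `fixed` (estimates and SEs), `varcomp`, `n`, `converged`,
#'   `random_used`, `covariate` (screening result), `season`, `notes`.
#' @export
fit_seasonal_model <- function(records, season = c("summer_fall", "spring"),
                               covariate = NULL, interaction = TRUE,
                               screen_alpha = 0.05, method = "REML",
                               type = "II") {
  season <- match.arg(season)
  resp <- rate_column(season)
  stopifnot(resp %in% names(records), nrow(records) > 0)
  records$region <- factor(records$region)
  records$photoperiod <- factor(records$photoperiod)
  if (nlevels(records$region) < 2 || nlevels(records$photoperiod) < 2)
    stop("need at least 2 levels of region and photoperiod")

  scr <- NULL
  terms <- c("region", "photoperiod",
             if (interaction) "region:photoperiod")
  if (!identical(covariate, "none")) {
    scr <- screen_covariate(records, season, covariate, alpha = screen_alpha,
                            method = method)
    if (scr$decision == "keep") terms <- c(terms, scr$covariate)
  }
  d <- records
  if (!is.null(scr) && scr$decision == "keep")
    d <- d[complete.cases(d[c(resp, scr$covariate)]), ]
  fixed <- reformulate(terms, response = resp)
  fv <- fit_lme_cascade(fixed, d,
                        list(nested = ~ 1 | sub_population / family,
                             population = ~ 1 | sub_population),
                        method)
  fe <- if (inherits(fv$fit, "lme")) nlme::fixef(fv$fit) else coef(fv$fit)
  se <- sqrt(diag(vcov(fv$fit)))
  structure(list(anova = wald_table(fv$fit, type = type),
                 fixed = data.frame(term = names(fe), estimate = unname(fe),
                                    se = unname(se)[seq_along(fe)],
                                    stringsAsFactors = FALSE),
                 varcomp = variance_components(fv$fit),
                 n = nrow(d), converged = fv$converged,
                 random_used = fv$random_used,
                 covariate = scr, season = season, notes = fv$notes,
                 fit = fv$fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Mixed-effects ANOVA (Wald chi-square), response:",
      if (!is.null(x$season)) x$season else "", "\n")
  cat("  n =", x$n, " random structure:", x$random_used,
      if (!x$converged) " [fallback]" else "", "\n")
  tab <- x$anova
  tab$chisq <- round(tab$chisq, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$covariate))
    cat("  covariate", x$covariate$covariate, ":", x$covariate$decision,
        "(p =", signif(x$covariate$p, 3), ")\n")
  invisible(x)
}

#' One-way ANOVA for hatchling size across regions
#'
#' Classical one-way analysis of variance of individual hatchling head width
#' on region of origin (hatchlings from the northern-photoperiod batch only,
#' by design). Regions contributing fewer than two observations are excluded
#' with a warning. Degenerate inputs are resolved deterministically: zero
#' between- and within-group variance gives F = 0, p = 1; positive
#' between-group with zero within-group variance gives F = Inf, p = 0.
#'
#' @param hatchlings data.frame with columns `region` and `head_width_mm`.
#' @return A list with `F`, `df1`, `df2`, `p` and `n`.
#' @export
hatchling_anova <- function(hatchlings) {
  stopifnot(all(c("region", "head_width_mm") %in% names(hatchlings)))
  counts <- table(hatchlings$region)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding region(s) with < 2 hatchlings: ",
            paste(small, collapse = ", "))
    hatchlings <- hatchlings[!hatchlings$region %in% small, ]
  }
  hatchlings$region <- factor(as.character(hatchlings$region))
  if (nlevels(hatchlings$region) < 2) stop("need hatchlings from >= 2 regions")
  df1 <- nlevels(hatchlings$region) - 1L
  df2 <- nrow(hatchlings) - nlevels(hatchlings$region)
  # degeneracy guards, relative to the total sum of squares
  g <- split(hatchlings$head_width_mm, hatchlings$region)
  grand <- mean(hatchlings$head_width_mm)
  ss_b <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2, 1))
  ss_w <- sum(vapply(g, function(x) sum((x - mean(x))^2), 1))
  eps <- 1e-12 * max(ss_b + ss_w, 1e-300)
  if (ss_b <= eps && ss_w <= eps) {
    Fv <- 0; p <- 1
  } else if (ss_w <= eps) {
    Fv <- Inf; p <- 0
  } else {
    a <- suppressWarnings(anova(lm(head_width_mm ~ region,
                                   data = hatchlings)))
    Fv <- a[["F value"]][1]
    p <- a[["Pr(>F)"]][1]
  }
  list(F = Fv, df1 = df1, df2 = df2, p = p, n = nrow(hatchlings))
}

#' Mixed-effects ANOVA for field-collected adult size
#'
#' Adult head width against region of origin, sex and their interaction
#' (fixed) with a random population intercept; Type II Wald chi-square per
#' term. Also reports the male - female head-width contrast averaged over
#' regions, with its standard error.
#'
#' @param adults data.frame with columns `region`, `population`, `sex`
#'   (`"male"`/`"female"`), `head_width_mm`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param type Wald test type (default `"II"`).
#' @return A `"model_fit"` object; element `sex_contrast` holds the
#'   male - female estimate and SE.
#' @export
adult_size_model <- function(adults, method = "REML", type = "II") {
  stopifnot(all(c("region", "population", "sex", "head_width_mm") %in%
                  names(adults)))
  adults$region <- factor(adults$region)
  adults$sex <- factor(adults$sex)
  if (nlevels(adults$sex) < 2 || nlevels(adults$region) < 2)
    stop("need both sexes and >= 2 regions")
  fv <- fit_lme_cascade(head_width_mm ~ region * sex, adults,
                        list(population = ~ 1 | population), method)
  fe <- if (inherits(fv$fit, "lme")) nlme::fixef(fv$fit) else coef(fv$fit)
  V <- vcov(fv$fit)
  # male - female averaged over regions (treatment contrasts assumed)
  sex_lab <- grep("^sex", names(fe), value = TRUE)
  sex_lab <- sex_lab[!grepl(":", sex_lab)]
  int_lab <- grep(":sex", names(fe), value = TRUE)
  L <- setNames(numeric(length(fe)), names(fe))
  L[sex_lab] <- 1
  if (length(int_lab)) L[int_lab] <- 1 / nlevels(adults$region)
  est <- sum(L * fe)
  se <- sqrt(drop(t(L) %*% as.matrix(V)[names(fe), names(fe)] %*% L))
  sign_mf <- if (levels(adults$sex)[2] == "male") 1 else -1
  structure(list(anova = wald_table(fv$fit, type = type),
                 fixed = data.frame(term = names(fe), estimate = unname(fe),
                                    se = sqrt(diag(as.matrix(V)))[seq_along(fe)],
                                    stringsAsFactors = FALSE),
                 varcomp = variance_components(fv$fit),
                 sex_contrast = c(estimate = sign_mf * est, se = se),
                 n = nrow(adults), converged = fv$converged,
                 random_used = fv$random_used, season = "adult size",
                 covariate = NULL, notes = fv$notes, fit = fv$fit),
            class = "model_fit")
}

#' Regression of seasonal growth rate on hatchling size
#'
#' Ordinary least squares of an individual's seasonal growth rate on its
#' family-mean hatchling head width, restricted to the treatment group in
#' which hatchlings were measured (the northern photoperiod, by default).
#' Optionally aggregates to family means first.
#'
#' @param records a growth-rate table from [seasonal_rates()].
#' @param season `"summer_fall"` or `"spring"`.
#' @param treatment photoperiod level to restrict to (default `"northern"`).
#' @param aggregate_families regress family-mean rate on family hatch size
#'   instead of individual rates (default FALSE).
#' @return A list with `slope`, `intercept`, `r_squared`, `p` (slope test),
#'   `n` and `sign` of the slope.
#' @export
hatch_growth_regression <- function(records,
                                    season = c("summer_fall", "spring"),
                                    treatment = "northern",
                                    aggregate_families = FALSE) {
  season <- match.arg(season)
  resp <- rate_column(season)
  d <- records[records$photoperiod == treatment, c(resp, "hatch_size_mm",
                                                   "family")]
  d <- d[complete.cases(d[c(resp, "hatch_size_mm")]), ]
  if (aggregate_families) {
    d <- data.frame(
      hatch_size_mm = tapply(d$hatch_size_mm, d$family, mean),
      rate = tapply(d[[resp]], d$family, mean))
  } else {
    d$rate <- d[[resp]]
  }
  if (nrow(d) < 3) stop("need at least 3 observations for the regression")
  f <- lm(rate ~ hatch_size_mm, data = d)
  s <- summary(f)
  slope <- coef(f)[["hatch_size_mm"]]
  list(slope = slope, intercept = coef(f)[["(Intercept)"]],
       r_squared = s$r.squared, p = s$coefficients["hatch_size_mm", 4],
       n = nrow(d), sign = sign(slope))
}
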