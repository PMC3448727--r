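#' Season anchors for growth-rate extraction
#'
#' The two growth rates are the slopes of an individual's fitted trajectory at
#' a mid-summer/fall age and a mid-spring age. With measurement events at
#' winter-excluded ages 0, 42, 84 and 126, the defaults are day 21 (half-way
#' between events 1 and 2) and day 105 (half-way between events 3 and 4).
#'
#' @param summer_fall_day anchor age for the summer/fall rate (default 21).
#' @param spring_day anchor age for the spring rate (default 105).
#' @param winter_days length of the winter pause excluded from the age axis
#'   (default 14).
#' @return An object of class `"season_anchors"`.
#' @export
season_anchors <- function(summer_fall_day = 21, spring_day = 105,
                           winter_days = 14) {
  stopifnot(summer_fall_day > 0, spring_day > summer_fall_day,
            winter_days >= 0)
  structure(list(summer_fall_day = summer_fall_day, spring_day = spring_day,
                 winter_days = winter_days), class = "season_anchors")
}

#' Winter-excluded age
#'
#' No growth occurs during the winter blackout, so individuals are considered
#' the same age at its start and end: calendar day offsets inside the winter
#' window map to the winter-start age, and later offsets have the full winter
#' length subtracted. The mapping is continuous and non-decreasing.
#'
#' @param day_offset days since hatching on the raw calendar axis (vector).
#' @param winter_start calendar day offset at which winter begins.
#' @param winter_days winter length in days (default 14).
#' @return Winter-excluded ages in days.
#' @examples
#' winter_adjusted_age(c(30, 70, 80), winter_start = 63)
#' @export
winter_adjusted_age <- function(day_offset, winter_start, winter_days = 14) {
  stopifnot(winter_days >= 0, winter_start >= 0)
  ifelse(day_offset < winter_start, day_offset,
         pmax(winter_start, day_offset - winter_days))
}

#' Fit a cubic growth trajectory on log head width
#'
#' Least-squares polynomial L(t) = b0 + b1 t + b2 t^2 + b3 t^3 on log head
#' width against winter-excluded age. With four distinct ages the cubic
#' interpolates the data exactly; with fewer the degree is reduced to
#' (number of distinct ages - 1) and the fit flagged as non-interpolating.
#' Ages are centred internally for conditioning and the coefficients reported
#' back on the original age axis.
#'
#' @param age_days winter-excluded ages in days.
#' @param head_width_mm head widths in mm, strictly positive.
#' @param log_base base of the log transform (default `exp(1)`); only
#'   rescales coefficients and slopes.
#' @return An object of class `"trajectory_fit"`: list with `coefficients`
#'   (b0..b3, higher orders zero when the degree is reduced), `n_points`,
#'   `degree`, `interpolating` (TRUE iff fitted to 4 distinct ages),
#'   `log_base` and `age_range`.
#' @export
fit_log_cubic <- function(age_days, head_width_mm, log_base = exp(1)) {
  ok <- is.finite(age_days) & is.finite(head_width_mm)
  age_days <- age_days[ok]; head_width_mm <- head_width_mm[ok]
  if (any(head_width_mm <= 0)) stop("head widths must be positive")
  if (length(unique(age_days)) < 2)
    stop("need at least 2 measurements at distinct ages")
  deg <- min(3L, length(unique(age_days)) - 1L)
  ctr <- mean(age_days)
  u <- age_days - ctr
  L <- log(head_width_mm, base = log_base)
  X <- outer(u, 0:deg, "^")
  cc <- if (nrow(X) == ncol(X)) solve(X, L) else qr.solve(X, L)
  # shift back from the centred axis: sum_k c_k (t - ctr)^k
  b <- numeric(4)
  for (k in 0:deg) {
    j <- 0:k
    b[j + 1] <- b[j + 1] + cc[k + 1] * choose(k, j) * (-ctr)^(k - j)
  }
  structure(list(coefficients = stats::setNames(b, paste0("b", 0:3)),
                 n_points = length(age_days), degree = deg,
                 interpolating = (deg == 3L &&
                                    length(unique(age_days)) == 4L &&
                                    length(age_days) == 4L),
                 log_base = log_base,
                 age_range = range(age_days)),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("Cubic trajectory fit (log head width vs age)\n")
  cat("  degree:", x$degree, " points:", x$n_points,
      " interpolating:", x$interpolating, "\n")
  print(round(x$coefficients, 8))
  invisible(x)
}

#' Slope of a fitted trajectory at a given age
#'
#' The instantaneous growth rate d(log head width)/d(age):
#' b1 + 2 b2 t + 3 b3 t^2. Ages outside the fitted range are extrapolations
#' and trigger a warning, but the value is still returned.
#'
#' @param fit a [fit_log_cubic()] result.
#' @param day age(s) in days at which to evaluate the slope.
#' @return Growth rate(s) in log units per day (same log base as the fit).
#' @export
slope_at <- function(fit, day) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (any(day < fit$age_range[1] | day > fit$age_range[2]))
    warning("slope evaluated outside the fitted age range (extrapolation)")
  b <- fit$coefficients
  unname(b[2] + 2 * b[3] * day + 3 * b[4] * day^2)
}

measurement_cols <- c("individual_id", "family", "sub_population", "region",
                      "photoperiod", "event_index", "age_days",
                      "head_width_mm")

#' Validate a larval measurement table
#'
#' Checks the schema expected by [seasonal_rates()]: required columns,
#' positive head widths, event indices in 1..4, strictly increasing ages
#' within each individual, and non-missing design labels. All violations are
#' reported together.
#'
#' @param measurements a data.frame of larval measurements.
#' @return The validated data.frame, invisibly. Errors with an itemised
#'   message on any violation.
#' @export
validate_measurements <- function(measurements) {
  problems <- character(0)
  missing_cols <- setdiff(measurement_cols, names(measurements))
  if (length(missing_cols))
    problems <- c(problems, paste("missing columns:",
                                  paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols)) {
    if (any(!is.finite(measurements$head_width_mm) |
              measurements$head_width_mm <= 0))
      problems <- c(problems, "head_width_mm must be positive and finite")
    if (any(!measurements$event_index %in% 1:4))
      problems <- c(problems, "event_index must be in 1..4")
    lab <- measurements[c("individual_id", "family", "sub_population",
                          "region", "photoperiod")]
    if (any(is.na(lab)) || any(unlist(lapply(lab, as.character)) == ""))
      problems <- c(problems, "design labels must be non-missing")
    bad_age <- vapply(split(measurements$age_days[order(measurements$event_index)],
                            measurements$individual_id[order(measurements$event_index)]),
                      function(a) any(diff(a) <= 0), logical(1))
    if (any(bad_age))
      problems <- c(problems,
                    paste("ages not strictly increasing for individual(s):",
                          paste(utils::head(names(bad_age)[bad_age], 5),
                                collapse = ", ")))
  }
  if (length(problems))
    stop("invalid measurement table:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(measurements)
}

#' Seasonal growth rates for every individual
#'
#' Fits each individual's cubic trajectory on log head width over
#' winter-excluded age and extracts the summer/fall and spring growth rates
#' as the slopes at the season anchors. Attaches the two covariates used for
#' screening: the family-mean hatchling head width (from `hatchlings` when
#' supplied, otherwise the family mean of the age-0 measurements) and the
#' individual's size at day 84. Individuals with fewer than two measurements
#' at distinct ages are excluded and counted in the `"excluded"` attribute.
#'
#' @param measurements a measurement table (see [validate_measurements()]).
#' @param hatchlings optional hatchling table with columns `family`, `region`,
#'   `head_width_mm`, used for the family-mean hatch-size covariate.
#' @param anchors a [season_anchors()] object.
#' @param log_base log base for the trajectory fits.
#' @return A data.frame with one row per individual: design labels,
#'   `summer_fall_rate`, `spring_rate` (d log head width / day),
#'   `hatch_size_mm`, `size_day84_mm`, `n_points`, `interpolating`.
#'   Attributes: `excluded` (number of dropped individuals), `log_base`,
#'   `anchors`.
#' @export
seasonal_rates <- function(measurements, hatchlings = NULL,
                           anchors = season_anchors(), log_base = exp(1)) {
  validate_measurements(measurements)
  hatch_mean <- NULL
  if (!is.null(hatchlings)) {
    stopifnot(all(c("family", "head_width_mm") %in% names(hatchlings)))
    hatch_mean <- tapply(hatchlings$head_width_mm, hatchlings$family, mean)
  } else {
    m0 <- measurements[measurements$age_days == 0, ]
    if (nrow(m0)) hatch_mean <- tapply(m0$head_width_mm, m0$family, mean)
  }
  per_ind <- split(measurements, measurements$individual_id)
  excluded <- 0L
  rows <- lapply(per_ind, function(d) {
    d <- d[order(d$age_days), ]
    if (length(unique(d$age_days)) < 2) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    fit <- fit_log_cubic(d$age_days, d$head_width_mm, log_base = log_base)
    w84 <- d$head_width_mm[d$age_days == 84]
    data.frame(individual_id = d$individual_id[1], family = d$family[1],
               sub_population = d$sub_population[1], region = d$region[1],
               photoperiod = d$photoperiod[1],
               summer_fall_rate = slope_at(fit, anchors$summer_fall_day),
               spring_rate = slope_at(fit, anchors$spring_day),
               hatch_size_mm = if (!is.null(hatch_mean) &&
                                     as.character(d$family[1]) %in% names(hatch_mean))
                 unname(hatch_mean[as.character(d$family[1])]) else NA_real_,
               size_day84_mm = if (length(w84)) w84[1] else NA_real_,
               n_points = fit$n_points, interpolating = fit$interpolating,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "log_base") <- log_base
  attr(out, "anchors") <- anchors
  out
}
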