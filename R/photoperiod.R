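#' Solar declination
#'
#' Low-precision solar declination from the fractional-year Fourier expansion
#' (Spencer 1971), evaluated at solar noon. Accuracy is about 0.2 degrees,
#' which translates to a few minutes of day length at boreal latitudes --
#' ample for rearing-chamber photoperiod programming.
#'
#' @param date a `Date` vector (coerced with [as.Date()]).
#' @return Numeric vector of declinations in degrees, within about
#'   \[-23.45, 23.45\].
#' @examples
#' solar_declination(as.Date("2010-06-21"))
#' @export
solar_declination <- function(date) {
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  d <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  d * 180 / pi
}

#' Hours per day the sun spends above a given altitude
#'
#' Classical hour-angle computation: the sun is above altitude `a` while
#' `cos(H) <= (sin a - sin phi sin delta) / (cos phi cos delta)`. Days on
#' which the sun never crosses the altitude return the polar sentinels 24
#' (never below, "polar day" with respect to that altitude) or 0 (never
#' above).
#'
#' @param latitude degrees north, in \[-90, 90\].
#' @param date a `Date` vector.
#' @param altitude sun-centre altitude in degrees, in (-90, 90). Use -0.833
#'   for sunrise/sunset (refraction plus solar radius), -6 for the civil
#'   twilight boundary.
#' @return Numeric vector of durations in decimal hours, in \[0, 24\].
#' @export
altitude_crossing_hours <- function(latitude, date, altitude) {
  if (any(!is.finite(latitude)) || any(latitude < -90 | latitude > 90))
    stop("`latitude` must lie in [-90, 90]")
  if (any(!is.finite(altitude)) || any(altitude <= -90 | altitude >= 90))
    stop("`altitude` must lie in (-90, 90)")
  delta <- solar_declination(date) * pi / 180
  phi <- latitude * pi / 180
  a <- altitude * pi / 180
  cosH <- (sin(a) - sin(phi) * sin(delta)) / (cos(phi) * cos(delta))
  crossing <- 2 * acos(pmin(pmax(cosH, -1), 1)) * 180 / pi / 15
  ifelse(cosH <= -1, 24, ifelse(cosH >= 1, 0, crossing))
}

#' Twilight rule for the light phase
#'
#' Defines what counts as "light" in a chamber program: time above the
#' rise/set altitude plus a fraction of each twilight period (the interval
#' between the twilight boundary and the rise/set altitude). The default is
#' the civil-twilight rule with half of each twilight lit.
#'
#' @param rise_set_altitude sunrise/sunset sun-centre altitude, degrees
#'   (default -0.833).
#' @param twilight_altitude twilight boundary, degrees (default -6, civil
#'   twilight). Must be below `rise_set_altitude`.
#' @param twilight_fraction fraction of each twilight period counted as
#'   light, in \[0, 1\] (default 0.5).
#' @return An object of class `"twilight_rule"`.
#' @export
twilight_rule <- function(rise_set_altitude = -0.833, twilight_altitude = -6,
                          twilight_fraction = 0.5) {
  stopifnot(is.numeric(rise_set_altitude), is.numeric(twilight_altitude),
            is.numeric(twilight_fraction))
  if (!(twilight_altitude < rise_set_altitude && rise_set_altitude <= 0))
    stop("need twilight_altitude < rise_set_altitude <= 0")
  if (twilight_fraction < 0 || twilight_fraction > 1)
    stop("`twilight_fraction` must lie in [0, 1]")
  structure(list(rise_set_altitude = rise_set_altitude,
                 twilight_altitude = twilight_altitude,
                 twilight_fraction = twilight_fraction),
            class = "twilight_rule")
}

#' Light-phase duration at a latitude and date
#'
#' Daylight (sun above the rise/set altitude) plus `twilight_fraction` of the
#' total twilight time (sun between the twilight boundary and the rise/set
#' altitude). At high latitudes in midsummer the sun may set without ever
#' reaching the twilight boundary; the whole dark period is then twilight and
#' contributes `twilight_fraction * (24 - daylight)` (regime
#' `"all_night_twilight"`). In polar night the light phase consists of the
#' twilight contribution only, possibly 0.
#'
#' @param latitude degrees north; recycled against `date`.
#' @param date a `Date` vector.
#' @param rule a [twilight_rule()].
#' @return A data.frame with columns `latitude`, `date`, `light_hours`,
#'   `dark_hours` (always summing to 24) and `regime` (one of `"normal"`,
#'   `"polar_day"`, `"polar_night"`, `"all_night_twilight"`).
#' @examples
#' light_phase(64, as.Date("2010-07-10"))
#' @export
light_phase <- function(latitude, date, rule = twilight_rule()) {
  stopifnot(inherits(rule, "twilight_rule"))
  date <- as.Date(date)
  n <- max(length(latitude), length(date))
  latitude <- rep_len(latitude, n)
  date <- rep_len(date, n)
  day <- altitude_crossing_hours(latitude, date, rule$rise_set_altitude)
  above_twi <- altitude_crossing_hours(latitude, date, rule$twilight_altitude)
  light <- day + rule$twilight_fraction * (above_twi - day)
  regime <- rep("normal", n)
  regime[day >= 24] <- "polar_day"
  regime[day < 24 & above_twi >= 24] <- "all_night_twilight"
  regime[day <= 0] <- "polar_night"
  data.frame(latitude = latitude, date = date,
             light_hours = light, dark_hours = 24 - light,
             regime = regime, stringsAsFactors = FALSE)
}

#' Convert between decimal hours and h.mm duration notation
#'
#' Chamber programs and published L:D ratios quote durations as hours.minutes
#' ("h.mm"): 17.15 means 17 h 15 min, not 17.15 decimal hours. `to_hmm()`
#' rounds a decimal-hour duration to the nearest minute and encodes it as
#' `hours + minutes/100`; `from_hmm()` inverts the encoding.
#'
#' @param hours decimal hours in \[0, 24\].
#' @param hmm a duration in h.mm notation (minute part must be < 60).
#' @return `to_hmm()`: numeric vector in h.mm notation. `from_hmm()`: decimal
#'   hours. Round-tripping agrees to within half a minute.
#' @examples
#' to_hmm(17.25)    # 17.15, i.e. 17 h 15 min
#' from_hmm(22.06)  # 22.1 decimal hours
#' @export
to_hmm <- function(hours) {
  if (any(!is.finite(hours)) || any(hours < 0 | hours > 24))
    stop("`hours` must lie in [0, 24]")
  m <- round(hours * 60)
  (m %/% 60) + (m %% 60) / 100
}

#' @rdname to_hmm
#' @export
from_hmm <- function(hmm) {
  if (any(!is.finite(hmm)) || any(hmm < 0))
    stop("`hmm` must be a non-negative h.mm duration")
  h <- floor(hmm + 1e-9)
  m <- round((hmm - h) * 100)
  if (any(m >= 60)) stop("minute part of an h.mm duration must be < 60")
  h + m / 60
}

#' Weekly-updated photoperiod schedule
#'
#' Rearing chambers are typically reprogrammed on a fixed weekday rather than
#' daily. Returns one row per calendar day where the applied light phase is
#' that of the most recent update day (the start date counts as the initial
#' setting). `mode = "daily"` tracks the sky exactly instead.
#'
#' @param latitude degrees north.
#' @param start_date,end_date schedule window (`Date`), start <= end.
#' @param rule a [twilight_rule()].
#' @param update_weekday ISO weekday number of the update day (1 = Monday ...
#'   7 = Sunday); default 6, Saturday.
#' @param mode `"weekly"` (piecewise-constant between updates, default) or
#'   `"daily"`.
#' @return A data.frame with columns `date`, `applied_date` (the day whose
#'   light phase is in force), `light_hours`, `dark_hours`, `regime`.
#' @export
weekly_schedule <- function(latitude, start_date, end_date,
                            rule = twilight_rule(), update_weekday = 6,
                            mode = c("weekly", "daily")) {
  mode <- match.arg(mode)
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (start_date > end_date) stop("start_date must not exceed end_date")
  dates <- seq(start_date, end_date, by = "day")
  if (mode == "daily") {
    applied <- dates
  } else {
    wd <- as.integer(strftime(dates, "%u"))
    applied <- as.Date(rep(NA_integer_, length(dates)), origin = "1970-01-01")
    current <- start_date  # initial chamber setting
    for (i in seq_along(dates)) {
      if (wd[i] == update_weekday) current <- dates[i]
      applied[i] <- current
    }
  }
  lp <- light_phase(latitude, applied, rule)
  data.frame(date = dates, applied_date = applied,
             light_hours = lp$light_hours, dark_hours = lp$dark_hours,
             regime = lp$regime, stringsAsFactors = FALSE)
}

#' Full experimental treatment schedule with winter blackout and spring jump
#'
#' Day-by-day chamber program for one photoperiod treatment: the light phase
#' tracks the real calendar from the start date until the day before winter
#' onset; winter is a fixed-length total blackout at the cold temperature;
#' from the first spring day the mapped solar date restarts at
#' `spring_solar_date` and advances daily. Temperatures step
#' warm -> mild (the day before winter) -> cold (winter) -> mild (spring
#' onset) -> warm (after `mild_days` days of spring, i.e. when the mapped
#' date reaches `spring_solar_date + mild_days`).
#'
#' @param treatment_latitude latitude the chamber mimics, degrees north.
#' @param start_date first day of the program (default "2010-07-10").
#' @param winter_start first blackout day (default "2010-10-09").
#' @param winter_days blackout length in days (default 14).
#' @param spring_solar_date solar date the first spring day maps to
#'   (default "2011-04-09").
#' @param end_date last day of the program (default "2011-01-31").
#' @param temp_warm,temp_mild,temp_cold temperatures (deg C) for the three
#'   plateaus (defaults 22.5, 16, 5).
#' @param mild_days days at the mild temperature after spring onset before
#'   returning to warm (default 15).
#' @param rule a [twilight_rule()].
#' @param update `"daily"` (exact-date tracking, default) or `"weekly"`
#'   (Saturday chamber updates) for the non-winter phases.
#' @param update_weekday ISO weekday of weekly updates (default 6, Saturday).
#' @return A data.frame with one row per calendar day: `calendar_date`,
#'   `mapped_solar_date`, `latitude`, `light_hours`, `dark_hours`,
#'   `regime_flag`, `temperature_c`, `phase`
#'   (`"summer_fall"`/`"winter"`/`"spring"`).
#' @export
experiment_schedule <- function(treatment_latitude,
                                start_date = "2010-07-10",
                                winter_start = "2010-10-09",
                                winter_days = 14,
                                spring_solar_date = "2011-04-09",
                                end_date = "2011-01-31",
                                temp_warm = 22.5, temp_mild = 16,
                                temp_cold = 5, mild_days = 15,
                                rule = twilight_rule(),
                                update = c("daily", "weekly"),
                                update_weekday = 6) {
  update <- match.arg(update)
  start_date <- as.Date(start_date)
  winter_start <- as.Date(winter_start)
  spring_solar_date <- as.Date(spring_solar_date)
  end_date <- as.Date(end_date)
  spring_start <- winter_start + winter_days
  stopifnot(start_date < winter_start, spring_start <= end_date)

  dates <- seq(start_date, end_date, by = "day")
  phase <- ifelse(dates < winter_start, "summer_fall",
                  ifelse(dates < spring_start, "winter", "spring"))
  mapped <- dates
  mapped[phase == "spring"] <-
    spring_solar_date + as.numeric(dates[phase == "spring"] - spring_start)

  sched <- function(d_cal, d_map) {
    if (length(d_cal) == 0)
      return(data.frame(light_hours = numeric(0), dark_hours = numeric(0),
                        regime = character(0)))
    if (update == "daily") {
      light_phase(treatment_latitude, d_map, rule)[c("light_hours",
                                                     "dark_hours", "regime")]
    } else {
      wd <- as.integer(strftime(d_cal, "%u"))
      applied <- d_map
      cur <- d_map[1]
      for (i in seq_along(d_cal)) {
        if (wd[i] == update_weekday) cur <- d_map[i]
        applied[i] <- cur
      }
      light_phase(treatment_latitude, applied, rule)[c("light_hours",
                                                       "dark_hours", "regime")]
    }
  }

  out <- data.frame(calendar_date = dates, mapped_solar_date = mapped,
                    latitude = treatment_latitude,
                    light_hours = NA_real_, dark_hours = NA_real_,
                    regime_flag = NA_character_,
                    temperature_c = NA_real_, phase = phase,
                    stringsAsFactors = FALSE)
  for (ph in c("summer_fall", "spring")) {
    sel <- phase == ph
    lp <- sched(dates[sel], mapped[sel])
    out$light_hours[sel] <- lp$light_hours
    out$dark_hours[sel] <- lp$dark_hours
    out$regime_flag[sel] <- lp$regime
  }
  wsel <- phase == "winter"
  out$light_hours[wsel] <- 0
  out$dark_hours[wsel] <- 24
  out$regime_flag[wsel] <- "winter_blackout"

  out$temperature_c <- temp_warm
  out$temperature_c[dates == winter_start - 1] <- temp_mild  # step-down day
  out$temperature_c[wsel] <- temp_cold
  spring_mild <- phase == "spring" &
    mapped < spring_solar_date + mild_days
  out$temperature_c[spring_mild] <- temp_mild
  out
}
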