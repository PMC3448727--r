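test_that("solar declination hits the solstice extremes and the equinox", {
  expect_equal(solar_declination(as.Date("2010-06-21")), 23.4, tolerance = 0.01)
  expect_equal(solar_declination(as.Date("2010-12-21")), -23.4, tolerance = 0.01)
  expect_lt(abs(solar_declination(as.Date("2010-03-21"))), 1)
  year <- seq(as.Date("2010-01-01"), as.Date("2010-12-31"), by = "day")
  d <- solar_declination(year)
  expect_true(all(abs(d) < 23.5))
  expect_lt(max(abs(diff(d))), 0.5) # continuous over the year
})

test_that("altitude crossings return polar sentinels where the sun never crosses", {
  expect_equal(altitude_crossing_hours(67, as.Date("2010-06-21"), -0.833), 24)
  expect_equal(altitude_crossing_hours(70, as.Date("2010-12-21"), -0.833), 0)
  # at 64N on 10 July the sun sets but never reaches civil darkness
  expect_equal(altitude_crossing_hours(64, as.Date("2010-07-10"), -6), 24)
  expect_lt(altitude_crossing_hours(64, as.Date("2010-07-10"), -0.833), 24)
  # equator at equinox: close to 12 h (slightly more through refraction)
  expect_equal(altitude_crossing_hours(0, as.Date("2010-03-20"), -0.833),
               12.1, tolerance = 0.05)
  expect_error(altitude_crossing_hours(95, as.Date("2010-06-21"), -0.833),
               "latitude")
  expect_error(altitude_crossing_hours(52, as.Date("2010-06-21"), -95),
               "altitude")
})

test_that("light and dark hours always sum to 24", {
  grid <- expand.grid(lat = c(-67, -30, 0, 30, 52, 62, 64, 67),
                      date = seq(as.Date("2010-01-05"), as.Date("2011-12-20"),
                                 by = "37 days"))
  lp <- light_phase(grid$lat, grid$date)
  expect_equal(lp$light_hours + lp$dark_hours, rep(24, nrow(grid)))
  expect_true(all(lp$light_hours >= 0 & lp$light_hours <= 24))
})

test_that("light phase is symmetric about the solstice to within 15 minutes", {
  solstice <- as.Date("2010-06-21")
  for (off in c(5, 20, 45, 80)) {
    a <- light_phase(52, solstice - off)$light_hours
    b <- light_phase(52, solstice + off)$light_hours
    expect_lt(abs(a - b), 0.25)
  }
})

test_that("midsummer light phase is non-decreasing in latitude", {
  lats <- seq(52, 67, by = 1)
  lp <- light_phase(lats, as.Date("2010-07-10"))
  expect_true(all(diff(lp$light_hours) >= 0))
})

test_that("twilight fraction 0 gives plain daylight; vanishing twilight band too", {
  d <- as.Date("2010-08-15")
  day <- altitude_crossing_hours(52, d, -0.833)
  expect_equal(light_phase(52, d, twilight_rule(twilight_fraction = 0))$light_hours,
               day)
  narrow <- twilight_rule(rise_set_altitude = -0.833,
                          twilight_altitude = -0.834)
  expect_equal(light_phase(52, d, narrow)$light_hours, day, tolerance = 1e-3)
  expect_error(twilight_rule(rise_set_altitude = -6, twilight_altitude = -0.833))
  expect_error(twilight_rule(twilight_fraction = 1.5))
})

test_that("engine agrees with an independent solar oracle within 5 minutes", {
  dates <- seq(as.Date("2010-01-15"), as.Date("2011-12-15"), by = "2 months")
  for (lat in c(-60, 0, 40, 52, 64, 67)) {
    for (d in as.list(dates)) {
      ours <- light_phase(lat, d)$light_hours
      theirs <- oracle_light(lat, d)
      expect_lt(abs(ours - theirs), 5 / 60)
    }
  }
})

test_that("h.mm notation converts and round-trips to the nearest minute", {
  expect_equal(to_hmm(17.25), 17.15)
  expect_equal(to_hmm(24), 24.00)
  expect_equal(to_hmm(11.433), 11.26)
  expect_equal(from_hmm(17.15), 17.25)
  x <- runif(50, 0, 24)
  expect_true(all(abs(from_hmm(to_hmm(x)) - x) <= 1 / 120 + 1e-9))
  expect_error(from_hmm(17.78), "minute")
  expect_error(to_hmm(25), "24")
})

test_that("weekly schedules are piecewise constant between Saturday updates", {
  # Sunday 11 July to Friday 16 July 2010: no Saturday inside
  ws <- weekly_schedule(52, as.Date("2010-07-11"), as.Date("2010-07-16"))
  expect_equal(length(unique(ws$light_hours)), 1L)
  # across July-August at 52N, updated values decrease after the solstice
  ws <- weekly_schedule(52, as.Date("2010-07-10"), as.Date("2010-09-01"))
  upd <- ws$light_hours[!duplicated(ws$applied_date)]
  expect_true(all(diff(upd) <= 0))
  # the northern treatment is always lighter than the southern in this window
  wn <- weekly_schedule(64, as.Date("2010-07-10"), as.Date("2010-09-01"))
  expect_true(all(wn$light_hours >= ws$light_hours))
})

test_that("experiment schedule encodes the winter blackout and spring jump", {
  sch <- experiment_schedule(52)
  row <- function(d) sch[sch$calendar_date == as.Date(d), ]
  # winter: total darkness at 5 degrees
  w <- row("2010-10-15")
  expect_equal(w$light_hours, 0)
  expect_equal(w$temperature_c, 5)
  expect_equal(w$regime_flag, "winter_blackout")
  # the day before winter steps down to the mild temperature, lights still on
  pre <- row("2010-10-08")
  expect_equal(pre$temperature_c, 16)
  expect_gt(pre$light_hours, 0)
  # spring onset maps 23 Oct to 9 Apr and holds the mild temperature
  sp <- row("2010-10-23")
  expect_equal(sp$mapped_solar_date, as.Date("2011-04-09"))
  expect_equal(sp$temperature_c, 16)
  expect_equal(to_hmm(sp$light_hours), 14.04, tolerance = 0.101)
  sp64 <- experiment_schedule(64)
  s <- sp64[sp64$calendar_date == as.Date("2010-10-23"), ]
  expect_equal(to_hmm(s$light_hours), 15.14, tolerance = 0.101)
  # warm again once the mapped date reaches 24 April (15 spring days at 16 C)
  expect_equal(row("2010-11-06")$temperature_c, 16)
  expect_equal(row("2010-11-07")$temperature_c, 22.5)
  expect_equal(row("2010-11-07")$mapped_solar_date, as.Date("2011-04-24"))
  # mapped date advances by one day everywhere except the winter jump
  step <- as.numeric(diff(sch$mapped_solar_date))
  jumps <- which(step != 1)
  expect_equal(length(jumps), 1L)
  expect_equal(sch$calendar_date[jumps + 1], as.Date("2010-10-23"))
})

test_that("weekly chamber emulation holds each setting until the next Saturday", {
  sch <- experiment_schedule(52, update = "weekly")
  pre_winter <- sch[sch$phase == "summer_fall", ]
  runs <- rle(pre_winter$light_hours)
  expect_true(all(runs$lengths[-c(1, length(runs$lengths))] == 7))
})
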