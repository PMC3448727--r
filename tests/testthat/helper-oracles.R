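# Independent solar oracle: Meeus-style ecliptic-longitude declination plus
# minute-grid quadrature of the altitude curve. Shares no code path with the
# package's Fourier declination / closed-form hour-angle engine.
oracle_declination <- function(date) {
  n <- as.numeric(as.Date(date)) - as.numeric(as.Date("2000-01-01")) - 0.5
  g <- (357.528 + 0.9856003 * n) * pi / 180
  L <- 280.460 + 0.9856474 * n
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  asin(sin(23.439 * pi / 180) * sin(lambda)) * 180 / pi
}

# hours per day the sun spends above `altitude`, by counting minutes
oracle_hours_above <- function(latitude, date, altitude) {
  delta <- oracle_declination(date) * pi / 180
  phi <- latitude * pi / 180
  tmin <- seq(0, 24, by = 1 / 60)
  H <- (tmin - 12) * 15 * pi / 180
  sinalt <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(H)
  mean(sinalt > sin(altitude * pi / 180)) * 24
}

oracle_light <- function(latitude, date, fraction = 0.5) {
  day <- oracle_hours_above(latitude, date, -0.833)
  twi <- oracle_hours_above(latitude, date, -6)
  day + fraction * (twi - day)
}

# tiny measurement-table builder for trajectory tests
make_measurements <- function(widths_by_individual,
                              ages = c(0, 42, 84, 126)) {
  ids <- names(widths_by_individual)
  do.call(rbind, lapply(ids, function(id) {
    w <- widths_by_individual[[id]]
    data.frame(individual_id = id, family = paste0("F_", id),
               sub_population = "P1", region = "central",
               photoperiod = "northern",
               event_index = seq_along(w), age_days = ages[seq_along(w)],
               head_width_mm = w, stringsAsFactors = FALSE)
  }))
}

# balanced noisy growth-rate records with known fixed effects, no grouping
# structure beyond the labels (for model-level tests)
make_rate_records <- function(n_per_cell = 10, photo_shift = 0,
                              region_shift = c(0, 0, 0), sigma = 0.002,
                              base = 0.01, seed = 1) {
  set.seed(seed)
  regions <- c("central", "northern", "northernmost")
  g <- expand.grid(rep = seq_len(n_per_cell), region = regions,
                   photoperiod = c("southern", "northern"),
                   stringsAsFactors = FALSE)
  mu <- base + photo_shift * (g$photoperiod == "northern") +
    region_shift[match(g$region, regions)]
  data.frame(individual_id = paste0("I", seq_len(nrow(g))),
             family = paste0("F", (seq_len(nrow(g)) - 1) %% 6 + 1, "_",
                             g$region),
             sub_population = paste0("P", g$region),
             region = g$region, photoperiod = g$photoperiod,
             summer_fall_rate = mu + rnorm(nrow(g), 0, sigma),
             spring_rate = mu + rnorm(nrow(g), 0, sigma),
             hatch_size_mm = rnorm(nrow(g), 0.45, 0.02),
             size_day84_mm = rnorm(nrow(g), 1, 0.05),
             stringsAsFactors = FALSE)
}
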