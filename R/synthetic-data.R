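# Synthetic area-day datasets with known hazard and vulnerability truth.
#
# The generator emulates the structure of the study data the pipeline is
# designed for: a seasonal temperature cycle with autocorrelated noise and
# explicitly injected hot spells, plus daily non-accidental death counts per
# age group whose rate rises with the HWII of the covering heat-wave event,
# spread over lags 0-3 and confounded by day-of-week, holidays, humidity and
# a long-term trend. Spells are injected (not emergent) so the truth
# heat-wave calendar is known exactly, enabling parameter-recovery tests.

#' Ground-truth vulnerability function families
#'
#' A vulnerability truth maps an event's HWII (degree-days) to the excess
#' crude mortality rate (per person-day) it induces; the excess is shared
#' across lags 0-3 by the configuration's `lag_weights`.
#'
#' * `vuln_linear(slope)`: excess = slope * hwii.
#' * `vuln_quadratic(coef)`: excess = coef * hwii^2.
#' * `vuln_hockey(slope, breakpoint)`: 0 below the breakpoint, then
#'   slope * (hwii - breakpoint).
#' * `vuln_ushape(coef, trough)`: excess = coef * ((hwii - trough)^2 -
#'   trough^2); zero at no exposure, minimal at `trough` (a U shape whose
#'   minimum-mortality HWII is known, for centering checks).
#' * `vuln_null()`: identically zero.
#'
#' @param slope,coef,breakpoint,trough family parameters (rates per
#'   degree-day).
#' @return an object of class `vuln_truth`.
#' @export
vuln_linear <- function(slope) {
  structure(list(family = "linear", slope = slope), class = "vuln_truth")
}

#' @rdname vuln_linear
#' @export
vuln_quadratic <- function(coef) {
  structure(list(family = "quadratic", coef = coef), class = "vuln_truth")
}

#' @rdname vuln_linear
#' @export
vuln_hockey <- function(slope, breakpoint) {
  structure(list(family = "hockey", slope = slope, breakpoint = breakpoint),
            class = "vuln_truth")
}

#' @rdname vuln_linear
#' @export
vuln_ushape <- function(coef, trough) {
  structure(list(family = "ushape", coef = coef, trough = trough),
            class = "vuln_truth")
}

#' @rdname vuln_linear
#' @export
vuln_null <- function() {
  structure(list(family = "null"), class = "vuln_truth")
}

#' Evaluate a vulnerability truth at given HWII values
#' @param v a `vuln_truth` object.
#' @param x HWII values (degree-days).
#' @return excess crude mortality rates (per person-day).
#' @export
eval_vuln <- function(v, x) {
  stopifnot(inherits(v, "vuln_truth"))
  switch(v$family,
    null = rep(0, length(x)),
    linear = v$slope * x,
    quadratic = v$coef * x^2,
    hockey = v$slope * pmax(0, x - v$breakpoint),
    ushape = v$coef * ((x - v$trough)^2 - v$trough^2),
    stop("unknown vulnerability family")
  )
}

#' Simulation configuration
#'
#' Defaults describe a single temperate-climate urban area: a sinusoidal
#' seasonal temperature cycle peaking in mid-July, AR(1) day-to-day noise,
#' about two injected hot spells per summer, and two age groups (0-64 and
#' 65+) whose baseline daily mortality rates are of the order seen in
#' city-level surveillance (a few deaths per day per group for a population
#' of several hundred thousand).
#'
#' @param n_years number of simulated calendar years.
#' @param start_year first calendar year.
#' @param t_mean_annual annual mean temperature, degrees C.
#' @param t_seasonal_amplitude seasonal half-range, degrees C.
#' @param ar1_coef AR(1) coefficient of the temperature noise, in [0, 1).
#' @param noise_sd marginal standard deviation of the noise, degrees C (> 0).
#' @param spell_rate expected number of injected hot spells per year.
#' @param spell_excess temperature added on spell days, degrees C.
#' @param spell_duration_mean mean spell duration, days (geometric-like).
#' @param diurnal_half_range half the diurnal range: tmax = tmean + range,
#'   tmin = tmean - range.
#' @param baseline_rate named vector of baseline deaths per person-day for
#'   age groups `0-64` and `65+`.
#' @param dow_effects multiplicative day-of-week factors, Monday first (7).
#' @param holiday_effect multiplicative factor on public holidays.
#' @param trend_slope per-year multiplicative drift of the baseline rate.
#' @param mort_seasonal_amplitude relative amplitude of a winter-peaking
#'   mortality seasonality term (0 disables it; the within-year mortality
#'   seasonality of real populations is exposed as a knob, not asserted).
#' @param rh_mean,rh_sd relative humidity mean and sd, percent (clipped to
#'   [0, 100]).
#' @param api_mean,api_sd air pollution index mean and sd (Gamma-shaped).
#' @param vuln_truth named list of `vuln_truth` objects per age group.
#' @param lag_weights 4 non-negative weights summing to 1: the shares of the
#'   excess realized at lags 0..3.
#' @param population resident population, persons (constant over the run).
#' @param age_shares named fractions per age group, summing to 1.
#' @param truth_definition the [hw_definition()] under which the generator's
#'   injected events act on mortality.
#' @param seed integer seed governing all randomness of the dataset.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_years = 10L,
                       start_year = 2001L,
                       t_mean_annual = 17,
                       t_seasonal_amplitude = 12,
                       ar1_coef = 0.6,
                       noise_sd = 2,
                       spell_rate = 2,
                       spell_excess = 6,
                       spell_duration_mean = 4,
                       diurnal_half_range = 4,
                       baseline_rate = c("0-64" = 3.4e-06, "65+" = 1.4e-04),
                       dow_effects = c(1, 1, 1, 1, 1, 1.02, 1.02),
                       holiday_effect = 1.05,
                       trend_slope = 0.005,
                       mort_seasonal_amplitude = 0,
                       rh_mean = 75, rh_sd = 12,
                       api_mean = 60, api_sd = 20,
                       vuln_truth = list("0-64" = vuln_linear(1e-07),
                                         "65+" = vuln_linear(2e-06)),
                       lag_weights = c(0.4, 0.3, 0.2, 0.1),
                       population = 650000,
                       age_shares = c("0-64" = 0.9, "65+" = 0.1),
                       truth_definition = hw_definition("truth", "mean",
                                                        "absolute", 30, 2),
                       seed = 42L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  check_that(cfg$n_years >= 1 && cfg$n_years == round(cfg$n_years),
             "n_years", "must be a positive integer")
  check_that(cfg$ar1_coef >= 0 && cfg$ar1_coef < 1, "ar1_coef",
             "must lie in [0, 1)")
  check_that(cfg$noise_sd > 0, "noise_sd", "must be > 0")
  check_that(cfg$spell_rate >= 0, "spell_rate", "must be >= 0")
  check_that(cfg$spell_duration_mean >= 1, "spell_duration_mean",
             "must be >= 1 day")
  check_that(cfg$diurnal_half_range >= 0, "diurnal_half_range",
             "must be >= 0")
  check_that(abs(sum(cfg$age_shares) - 1) <= 1e-12, "age_shares",
             "must sum to 1")
  check_that(all(cfg$age_shares > 0), "age_shares", "must be positive")
  check_that(length(cfg$lag_weights) == 4L && all(cfg$lag_weights >= 0) &&
               abs(sum(cfg$lag_weights) - 1) <= 1e-12, "lag_weights",
             "must be 4 non-negative weights summing to 1")
  check_that(length(cfg$dow_effects) == 7L && all(cfg$dow_effects > 0),
             "dow_effects", "must be 7 positive factors")
  check_that(all(cfg$baseline_rate >= 0), "baseline_rate",
             "must be non-negative")
  check_that(identical(sort(names(cfg$baseline_rate)),
                       sort(names(cfg$age_shares))),
             "baseline_rate", "age-group names must match age_shares")
  check_that(all(names(cfg$age_shares) %in% names(cfg$vuln_truth)),
             "vuln_truth", "must name every age group")
  check_that(cfg$population > 0, "population", "must be positive")
  check_that(inherits(cfg$truth_definition, "hw_definition"),
             "truth_definition", "must be an hw_definition")
  check_that(is.numeric(cfg$seed) && abs(cfg$seed) < 2^31 - 10,
             "seed", "must be a 32-bit integer")
  invisible(cfg)
}

sim_dates <- function(cfg) {
  seq(as.Date(sprintf("%d-01-01", cfg$start_year)),
      as.Date(sprintf("%d-12-31", cfg$start_year + cfg$n_years - 1L)),
      by = "day")
}

#' Generate the daily temperature series
#'
#' tmean = seasonal sinusoid (peaking on day-of-year 196, mid-July) + AR(1)
#' noise with marginal sd `noise_sd` + `spell_excess` on injected spell days.
#' Spell counts are Poisson per year, spell starts fall in the warm season
#' (June-August), and durations are geometric with mean
#' `spell_duration_mean`. tmax/tmin are the mean plus/minus the diurnal
#' half-range, so tmin <= tmean <= tmax on every day.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return data frame `date`, `tmean`, `tmax`, `tmin` with the realized
#'   spell calendar attached as attribute `"spells"`.
#' @export
generate_temperature <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  dates <- sim_dates(cfg)
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- cfg$t_mean_annual +
    cfg$t_seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)

  with_seed(seed, {
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1_coef^2)
    z <- stats::rnorm(n, 0, innov_sd)
    e0 <- stats::rnorm(1, 0, cfg$noise_sd)
    noise <- as.numeric(stats::filter(z, cfg$ar1_coef, method = "recursive",
                                      init = e0))

    spell_day <- logical(n)
    spells <- list()
    years <- as.integer(format(dates, "%Y"))
    for (y in unique(years)) {
      n_sp <- stats::rpois(1, cfg$spell_rate)
      if (n_sp == 0) next
      warm <- which(years == y & doy >= 152 & doy <= 243)
      starts <- sort(sample(warm, n_sp, replace = TRUE))
      durs <- stats::rgeom(n_sp, 1 / cfg$spell_duration_mean) + 1L
      for (k in seq_len(n_sp)) {
        idx <- starts[k]:min(n, starts[k] + durs[k] - 1L)
        spell_day[idx] <- TRUE
        spells[[length(spells) + 1L]] <- data.frame(
          start = dates[starts[k]], duration = length(idx), year = y)
      }
    }
    spells <- if (length(spells)) do.call(rbind, spells) else
      data.frame(start = as.Date(character()), duration = integer(),
                 year = integer())

    tmean <- seasonal + noise + cfg$spell_excess * spell_day
    out <- data.frame(date = dates, tmean = tmean,
                      tmax = tmean + cfg$diurnal_half_range,
                      tmin = tmean - cfg$diurnal_half_range)
    attr(out, "spells") <- spells
    out
  })
}

#' Generate daily death counts per age group
#'
#' The expected rate of age group g on day t is
#' `baseline_rate_g * dow * holiday * trend * (1 + seasonality)` plus the
#' distributed-lag excess `sum_l lag_weights[l] * vuln_g(HWII of the event
#' covering day t-l)`; counts are Poisson with mean
#' `population * share_g * rate`. Negative intermediate rates (possible with
#' strongly negative truths) are clipped at zero with a warning. The
#' expected-rate matrix is attached as attribute `"expected_rate"` for
#' closed-form checks.
#'
#' @param cfg a [sim_config()].
#' @param tseries temperature series from [generate_temperature()].
#' @param hw_events events detected on `tseries` under the truth definition.
#' @param seed RNG seed.
#' @return data frame of daily counts, one column per age group.
#' @export
generate_mortality <- function(cfg, tseries, hw_events, seed = cfg$seed + 2L) {
  validate_sim_config(cfg)
  dates <- as.Date(tseries$date)
  n <- length(dates)
  hwii_t <- daily_hwii_series(tseries, hw_events)
  doy <- as.integer(format(dates, "%j"))
  dow <- (as.integer(format(dates, "%u")))  # 1 = Monday
  dow_f <- cfg$dow_effects[dow]
  hol_f <- ifelse(is_holiday(dates) == 1L, cfg$holiday_effect, 1)
  elapsed <- as.numeric(dates - dates[1]) / 365.25
  trend_f <- (1 + cfg$trend_slope)^elapsed
  season_f <- 1 + cfg$mort_seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)

  groups <- names(cfg$age_shares)
  rates <- matrix(0, n, length(groups), dimnames = list(NULL, groups))
  for (g in groups) {
    excess <- numeric(n)
    for (l in 0:3) {
      lagged <- c(numeric(l), hwii_t)[seq_len(n)]
      excess <- excess + cfg$lag_weights[l + 1] *
        eval_vuln(cfg$vuln_truth[[g]], lagged)
    }
    r <- cfg$baseline_rate[[g]] * dow_f * hol_f * trend_f * season_f + excess
    if (any(r < 0)) {
      warning(sprintf("%d negative intermediate rates clipped at 0 (group %s)",
                      sum(r < 0), g))
      r <- pmax(0, r)
    }
    rates[, g] <- r
  }

  deaths <- with_seed(seed, {
    m <- matrix(0L, n, length(groups), dimnames = list(NULL, groups))
    for (g in groups) {
      m[, g] <- stats::rpois(n, cfg$population * cfg$age_shares[[g]] *
                                rates[, g])
    }
    m
  })
  out <- as.data.frame(deaths)
  attr(out, "expected_rate") <- rates
  out
}

#' Generate a complete synthetic area dataset
#'
#' Composes the temperature and mortality generators with relative humidity,
#' an air pollution index, the fixed holiday calendar, and the population,
#' and records the generator-side truth (configuration echo, realized spell
#' calendar, and the truth heat-wave events that acted on mortality).
#'
#' @param cfg a [sim_config()].
#' @return an object of class `synthetic_dataset`: list with `records` (a
#'   daily data frame with columns `date`, `tmax`, `tmean`, `tmin`, `rh`,
#'   `api`, `holiday`, `deaths_0_64`, `deaths_65plus`, `population`) and
#'   `truth` (config echo, spells, events).
#' @export
generate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  tser <- generate_temperature(cfg, seed = cfg$seed)
  truth_thr <- resolve_threshold(tser, cfg$truth_definition)
  events <- detect_events(tser, cfg$truth_definition, threshold = truth_thr)
  deaths <- generate_mortality(cfg, tser, events, seed = cfg$seed + 2L)

  n <- nrow(tser)
  env <- with_seed(cfg$seed + 1L, {
    rh <- pmin(100, pmax(0, stats::rnorm(n, cfg$rh_mean, cfg$rh_sd)))
    shape <- (cfg$api_mean / cfg$api_sd)^2
    api <- stats::rgamma(n, shape = shape, scale = cfg$api_mean / shape)
    list(rh = rh, api = api)
  })

  records <- data.frame(
    date = tser$date,
    tmax = tser$tmax, tmean = tser$tmean, tmin = tser$tmin,
    rh = env$rh, api = env$api,
    holiday = is_holiday(tser$date),
    deaths_0_64 = deaths[["0-64"]],
    deaths_65plus = deaths[["65+"]],
    population = cfg$population
  )
  structure(
    list(records = records,
         truth = list(config = cfg, spells = attr(tser, "spells"),
                      events = events, threshold = truth_thr,
                      expected_rate = attr(deaths, "expected_rate"))),
    class = "synthetic_dataset"
  )
}

#' Write a synthetic dataset to disk
#'
#' One CSV of daily records plus a JSON truth sidecar (configuration echo and
#' the realized spell/event calendar).
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @param name file stem; writes `<name>.csv` and `<name>_truth.json`.
#' @return invisibly, the two paths.
#' @export
write_dataset <- function(ds, dir, name = "area") {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  records <- ds$records
  records$date <- format(records$date)
  utils::write.csv(records, csv, row.names = FALSE, quote = FALSE)

  cfg <- ds$truth$config
  cfg$truth_definition <- unclass(cfg$truth_definition)
  cfg$vuln_truth <- lapply(cfg$vuln_truth, unclass)
  truth <- list(
    config = unclass(cfg),
    threshold = ds$truth$threshold,
    spells = ds$truth$spells,
    events = as.data.frame(ds$truth$events)
  )
  js <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows")
  invisible(c(csv = csv, truth = js))
}

#' Read a daily-records CSV
#'
#' Validates the column contract of the synthetic/observed area files.
#'
#' @param path CSV path.
#' @return data frame with `date` parsed as `Date`.
#' @export
read_daily_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmax", "tmean", "tmin", "rh", "holiday",
            "deaths_0_64", "deaths_65plus", "population")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  x$date <- as.Date(x$date)
  x
}
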