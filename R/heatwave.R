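# Heat-wave definitions, event detection, and the heat wave intensity index.

#' Construct a heat-wave definition
#'
#' A heat-wave definition is a rule made of a temperature metric (daily mean,
#' maximum, or minimum), a threshold (absolute degrees Celsius or an empirical
#' percentile of the reference series), and a minimum consecutive-day
#' duration.
#'
#' @param id character key identifying the definition in a catalogue.
#' @param metric one of `"mean"`, `"max"`, `"min"`.
#' @param threshold_kind `"absolute"` (degrees Celsius) or `"percentile"`.
#' @param threshold_value threshold in degrees C, or a percentile in (0, 100).
#' @param min_duration minimum run length in days (>= 1).
#' @return an object of class `hw_definition`.
#' @examples
#' hw_definition("hw16", "max", "absolute", 35, 3)
#' @export
hw_definition <- function(id, metric = c("mean", "max", "min"),
                          threshold_kind = c("absolute", "percentile"),
                          threshold_value, min_duration = 1L) {
  metric <- match.arg(metric)
  threshold_kind <- match.arg(threshold_kind)
  check_that(is.character(id) && length(id) == 1L && nzchar(id), "id",
             "must be a non-empty string")
  check_that(is.numeric(threshold_value) && length(threshold_value) == 1L &&
               is.finite(threshold_value), "threshold_value",
             "must be a finite number")
  if (threshold_kind == "percentile") {
    check_that(threshold_value > 0 && threshold_value < 100, "threshold_value",
               "percentile must lie strictly in (0, 100)")
  }
  check_that(is.numeric(min_duration) && length(min_duration) == 1L &&
               min_duration >= 1 && min_duration == round(min_duration),
             "min_duration", "must be an integer >= 1")
  structure(
    list(id = id, metric = metric, threshold_kind = threshold_kind,
         threshold_value = as.numeric(threshold_value),
         min_duration = as.integer(min_duration)),
    class = "hw_definition"
  )
}

#' @export
print.hw_definition <- function(x, ...) {
  thr <- if (x$threshold_kind == "percentile") {
    sprintf("%gth percentile", x$threshold_value)
  } else {
    sprintf("%g degC", x$threshold_value)
  }
  cat(sprintf("<hw_definition %s> daily %s temperature > %s for >= %d day(s)\n",
              x$id, x$metric, thr, x$min_duration))
  invisible(x)
}

#' Load a catalogue of heat-wave definitions
#'
#' Reads a YAML catalogue (a list of entries with fields `id`, `metric`,
#' `threshold_kind`, `threshold_value`, `min_duration`). With no `path` the
#' packaged default catalogue of 16 definitions is returned: daily mean and
#' daily maximum temperature, percentile thresholds (92.5, 95, 97.5, 98) or
#' an absolute 35 degrees C, and minimum durations of 2 or 3 days.
#'
#' @param path optional path to a YAML catalogue file.
#' @return a named list of `hw_definition` objects, in file order.
#' @export
hw_catalogue <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hw_catalogue.yaml",
                                package = "heatrisk", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  defs <- lapply(raw, function(e) {
    hw_definition(e$id, e$metric, e$threshold_kind, e$threshold_value,
                  e$min_duration)
  })
  names(defs) <- vapply(defs, `[[`, character(1), "id")
  defs
}

metric_column <- function(defn) {
  switch(defn$metric, mean = "tmean", max = "tmax", min = "tmin")
}

get_metric <- function(series, defn) {
  col <- metric_column(defn)
  if (!col %in% names(series)) {
    stop(sprintf("series has no '%s' column required by metric '%s'",
                 col, defn$metric), call. = FALSE)
  }
  series[[col]]
}

#' Resolve a definition's threshold against a reference series
#'
#' Absolute thresholds are returned as given. Percentile thresholds are the
#' empirical quantile (linear interpolation, type 7) of the definition's
#' temperature metric over the full series supplied; the series passed here
#' *is* the reference period, which must therefore be chosen explicitly.
#'
#' @param series a daily-record data frame with `tmean`/`tmax`/`tmin` columns.
#' @param defn an [hw_definition()].
#' @return the threshold in degrees Celsius.
#' @export
resolve_threshold <- function(series, defn) {
  stopifnot(inherits(defn, "hw_definition"))
  if (defn$threshold_kind == "absolute") return(defn$threshold_value)
  x <- get_metric(series, defn)
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("empty reference series", call. = FALSE)
  unname(stats::quantile(x, probs = defn$threshold_value / 100, type = 7))
}

#' Detect heat-wave events in a daily series
#'
#' Finds maximal runs of consecutive days on which the definition's
#' temperature metric exceeds the resolved threshold, keeps runs at least
#' `min_duration` days long, and attaches each event's heat wave intensity
#' index (HWII): the sum over the event's days of the metric's exceedance
#' above the threshold, in degree-days.
#'
#' Exceedance is strict (`>`) by default, and "for over N consecutive days"
#' is read as duration >= N; both conventions can be switched.
#'
#' @param series daily records (must contain a `date` column of class `Date`
#'   and the metric column); days must be consecutive.
#' @param defn an [hw_definition()].
#' @param threshold optional pre-resolved threshold in degrees C; by default
#'   resolved from `series` via [resolve_threshold()].
#' @param comparison `">"` (default) or `">="`.
#' @param duration_rule `"ge"` (duration >= min_duration, default) or `"gt"`
#'   (strictly longer).
#' @return a data frame of class `hw_events` with columns `id`, `start`,
#'   `end`, `duration`, `hwii`, `year`, chronologically ordered, with the
#'   resolved threshold and the definition stored as attributes. Missing
#'   metric values are a hard error listing the offending dates.
#' @export
detect_events <- function(series, defn, threshold = NULL,
                          comparison = c(">", ">="),
                          duration_rule = c("ge", "gt")) {
  stopifnot(inherits(defn, "hw_definition"))
  comparison <- match.arg(comparison)
  duration_rule <- match.arg(duration_rule)
  if (!"date" %in% names(series)) stop("series must have a 'date' column")
  dates <- as.Date(series$date)
  if (nrow(series) > 1L && any(diff(dates) != 1L)) {
    stop("series days must be consecutive calendar days", call. = FALSE)
  }
  x <- get_metric(series, defn)
  if (anyNA(x)) {
    bad <- dates[is.na(x)]
    stop(sprintf("missing '%s' values on: %s", metric_column(defn),
                 paste(format(bad), collapse = ", ")), call. = FALSE)
  }
  thr <- threshold %||% resolve_threshold(series, defn)
  exceed <- if (comparison == ">") x > thr else x >= thr
  min_len <- if (duration_rule == "ge") defn$min_duration else defn$min_duration + 1L

  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  starts <- starts[keep]
  ends <- ends[keep]

  hwii <- vapply(seq_along(starts), function(i) {
    sum(x[starts[i]:ends[i]] - thr)
  }, numeric(1))

  ev <- data.frame(
    id = rep(defn$id, length(starts)),
    start = dates[starts],
    end = dates[ends],
    duration = as.integer(ends - starts + 1L),
    hwii = hwii,
    year = as.integer(format(dates[starts], "%Y")),
    stringsAsFactors = FALSE
  )
  if (length(starts)) ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("hw_events", "data.frame"),
            threshold = thr, definition = defn)
}

#' Heat wave intensity index of one event
#'
#' HWII = sum over the event's days of (metric - threshold), in degree-days.
#'
#' @param event a one-row event (anything with `start` and `end` dates).
#' @param series the daily series the event was detected in.
#' @param defn the [hw_definition()] used.
#' @param threshold resolved threshold; defaults to resolving from `series`.
#' @return HWII in degree-days (strictly positive for a valid event).
#' @export
compute_hwii <- function(event, series, defn, threshold = NULL) {
  thr <- threshold %||% resolve_threshold(series, defn)
  dates <- as.Date(series$date)
  idx <- which(dates >= as.Date(event$start) & dates <= as.Date(event$end))
  if (length(idx) == 0L) stop("event days not found in series", call. = FALSE)
  x <- get_metric(series, defn)[idx]
  sum(x - thr)
}

#' Daily HWII exposure series
#'
#' On each day covered by an event the series carries that event's *total*
#' HWII (constant across the event's days); all other days are 0. This is
#' the exposure variable entering the distributed-lag model.
#'
#' @param series daily records with a `date` column.
#' @param events an `hw_events` data frame.
#' @return numeric vector, one value per day of `series`.
#' @export
daily_hwii_series <- function(series, events) {
  dates <- as.Date(series$date)
  out <- numeric(length(dates))
  if (nrow(events) == 0L) return(out)
  for (i in seq_len(nrow(events))) {
    idx <- dates >= events$start[i] & dates <= events$end[i]
    out[idx] <- events$hwii[i]
  }
  out
}

#' Annual event frequency and pooled intensities
#'
#' Events are assigned to the calendar year of their start day. Every year
#' of the requested period appears, including zero-count years: the period
#' defines the denominator of the frequency model.
#'
#' @param events an `hw_events` data frame.
#' @param period integer vector `c(first_year, last_year)` (inclusive).
#' @return list with `annual` (data frame: `year`, `frequency`,
#'   `total_hwii`) and `intensities` (the pooled per-event HWII values).
#' @export
annual_stats <- function(events, period) {
  stopifnot(length(period) == 2L, period[2] >= period[1])
  years <- seq.int(period[1], period[2])
  freq <- vapply(years, function(y) sum(events$year == y), integer(1))
  tot <- vapply(years, function(y) sum(events$hwii[events$year == y]),
                numeric(1))
  list(
    annual = data.frame(year = years, frequency = freq, total_hwii = tot),
    intensities = events$hwii[events$year >= period[1] &
                                events$year <= period[2]]
  )
}

#' Crude mortality rate
#'
#' Deaths divided by the resident population: deaths per person-day when
#' applied to daily counts.
#'
#' @param deaths non-negative death counts (vectorized).
#' @param population positive population size(s).
#' @return crude rate(s), non-negative.
#' @export
crude_rate <- function(deaths, population) {
  check_that(all(deaths >= 0, na.rm = TRUE), "deaths", "must be non-negative")
  check_that(all(population > 0), "population", "must be positive")
  deaths / population
}
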