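# Event-based probabilistic risk assessment: Monte Carlo annual losses,
# exceedance-probability curves, AAL, PML, CMR/ASMR conversion, and future
# projection under a new hazard and age structure.

#' Population age structure
#'
#' @param shares named fractions per age group, strictly inside (0, 1) and
#'   summing to 1.
#' @param label source label (e.g. census year or scenario name).
#' @return object of class `age_structure`.
#' @export
age_structure <- function(shares, label = "") {
  check_that(all(shares > 0 & shares < 1), "shares", "must lie in (0, 1)")
  check_that(abs(sum(shares) - 1) <= 1e-12, "shares", "must sum to 1")
  check_that(!is.null(names(shares)) && all(nzchar(names(shares))),
             "shares", "must be named by age group")
  structure(list(shares = shares, label = label), class = "age_structure")
}

#' Construct a vulnerability curve object
#'
#' Grid representation of the cumulative excess crude mortality rate (per
#' person, accumulated over the lag window) as a function of event HWII,
#' with pointwise 95% bands. Usually produced by [cumulative_curve()];
#' constructing one directly supports analytic what-if curves.
#'
#' @param hwii grid of HWII values (degree-days), increasing.
#' @param central,lower95,upper95 curve bands at the grid (lower <= central
#'   <= upper pointwise).
#' @param center HWII at which the curve is zero.
#' @param age_group label.
#' @param observed_range HWII range the fit saw.
#' @param definition_id heat-wave definition label.
#' @return data frame of class `vulnerability_curve` with attributes
#'   `center`, `age_group`, `observed_range`, `definition_id`.
#' @export
vulnerability_curve <- function(hwii, central, lower95 = central,
                                upper95 = central, center = 0,
                                age_group = NA_character_,
                                observed_range = range(hwii),
                                definition_id = NA_character_) {
  stopifnot(length(hwii) >= 2, !is.unsorted(hwii, strictly = TRUE))
  stopifnot(length(central) == length(hwii),
            length(lower95) == length(hwii),
            length(upper95) == length(hwii))
  if (any(lower95 > central + 1e-12) || any(central > upper95 + 1e-12)) {
    stop("bands must satisfy lower95 <= central <= upper95 pointwise",
         call. = FALSE)
  }
  structure(
    data.frame(hwii = hwii, central = central, lower95 = lower95,
               upper95 = upper95),
    class = c("vulnerability_curve", "data.frame"),
    center = center, age_group = age_group,
    observed_range = observed_range, definition_id = definition_id
  )
}

#' Per-event mortality loss from the vulnerability curve
#'
#' Evaluates the selected band of the curve at the event's HWII: linear
#' interpolation on the grid, linear extrapolation beyond it with the
#' boundary segment's slope (consistent with the natural spline being
#' linear beyond its boundary knots). The result is floored at 0: the curve
#' is centered at the minimum-mortality HWII, so negative values are
#' sampling noise, not protective effects.
#'
#' @param hwii event intensity value(s), degree-days (> 0).
#' @param curve a `vulnerability_curve`.
#' @param band `"central"`, `"lower"`, or `"upper"`.
#' @return excess crude mortality rate per person per event (>= 0),
#'   vectorized over `hwii`.
#' @export
event_loss <- function(hwii, curve, band = c("central", "lower", "upper")) {
  band <- match.arg(band)
  col <- switch(band, central = "central", lower = "lower95",
                upper = "upper95")
  gx <- curve$hwii
  gy <- curve[[col]]
  n <- length(gx)
  y <- stats::approx(gx, gy, xout = hwii, rule = 2, ties = "ordered")$y
  below <- hwii < gx[1]
  above <- hwii > gx[n]
  if (any(below)) {
    s <- (gy[2] - gy[1]) / (gx[2] - gx[1])
    y[below] <- gy[1] + s * (hwii[below] - gx[1])
  }
  if (any(above)) {
    s <- (gy[n] - gy[n - 1]) / (gx[n] - gx[n - 1])
    y[above] <- gy[n] + s * (hwii[above] - gx[n])
  }
  pmax(0, y)
}

#' Monte Carlo simulation of annual heat-wave mortality losses
#'
#' Simulates `n_years` years of events from the hazard model (Poisson
#' frequency, Gamma intensity) and accumulates each event's loss through
#' every age group's vulnerability curve. The lower/central/upper bands use
#' common random numbers -- the same event stream -- so band ordering holds
#' year by year and the crude loss decomposes exactly across groups. Losses
#' are crude mortality rates per million persons per year.
#'
#' @param freq a `freq_model`.
#' @param intens an `intensity_model`.
#' @param curves named list of `vulnerability_curve`s, one per age group.
#' @param structure an [age_structure()] covering the same groups.
#' @param n_years simulated years (default 10000).
#' @param seed RNG seed.
#' @return object of class `risk_result`: per group, an `n_years x 3`
#'   matrix of annual CMR losses per million (columns `lower`, `central`,
#'   `upper`).
#' @export
simulate_losses <- function(freq, intens, curves, structure,
                            n_years = 10000L, seed = 1L) {
  stopifnot(inherits(freq, "freq_model"), inherits(intens, "intensity_model"),
            inherits(structure, "age_structure"))
  check_that(n_years >= 1, "n_years", "must be >= 1")
  groups <- names(curves)
  check_that(all(groups %in% names(structure$shares)), "curves",
             "age groups must appear in the age structure")

  ev <- with_seed(seed, {
    counts <- stats::rpois(n_years, freq$lambda)
    total <- sum(counts)
    list(counts = counts,
         intensity = if (total > 0)
           stats::rgamma(total, shape = intens$shape, scale = intens$scale)
         else numeric(0))
  })
  year_idx <- rep(seq_len(n_years), ev$counts)

  bands <- c("lower", "central", "upper")
  annual <- lapply(curves, function(curve) {
    m <- matrix(0, n_years, 3, dimnames = list(NULL, bands))
    if (length(ev$intensity)) {
      for (b in bands) {
        loss <- event_loss(ev$intensity, curve, band = b)
        agg <- rowsum(loss, year_idx)
        m[as.integer(rownames(agg)), b] <- agg
      }
    }
    m * 1e6  # per million persons
  })
  structure(
    list(annual = annual, structure = structure, n_years = n_years,
         seed = seed, freq = freq, intens = intens),
    class = "risk_result"
  )
}

#' Empirical loss exceedance probability curve
#'
#' EP(x) = fraction of simulated years whose loss strictly exceeds x,
#' evaluated at the sorted unique losses. Non-increasing; EP at the maximum
#' loss is 0.
#'
#' @param annual_losses numeric vector of simulated annual losses.
#' @return data frame `loss`, `ep`.
#' @export
ep_curve <- function(annual_losses) {
  n <- length(annual_losses)
  x <- sort(unique(annual_losses))
  counts <- as.numeric(table(factor(annual_losses, levels = x)))
  data.frame(loss = x, ep = (n - cumsum(counts)) / n)
}

#' Average annual loss
#' @param annual_losses simulated annual losses.
#' @return the arithmetic mean.
#' @export
aal <- function(annual_losses) mean(annual_losses)

#' Probable maximum loss at a return period
#'
#' The smallest simulated loss level whose exceedance probability is at
#' most `1/return_period` -- the lower limit on the loss at that
#' probability, i.e. the empirical `1 - 1/T` quantile (lower order
#' statistic convention).
#'
#' @param annual_losses simulated annual losses.
#' @param return_period return period T in years (>= 1).
#' @return the PML, in the units of `annual_losses`.
#' @export
pml <- function(annual_losses, return_period) {
  check_that(return_period >= 1, "return_period", "must be >= 1")
  n <- length(annual_losses)
  k <- max(1L, ceiling(n * (1 - 1 / return_period)))
  sort(annual_losses)[k]
}

#' Convert a crude-rate loss to an age-specific-rate loss
#'
#' CMR losses count a group's deaths against the *total* population; the
#' ASMR loss counts them against the group's own population:
#' `ASMR_g = CMR_g / share_g`. The inverse reconstitutes the crude loss as
#' `sum_g share_g * ASMR_g`.
#'
#' @param group_cmr_loss CMR loss(es) of one age group (per million of the
#'   total population).
#' @param structure an [age_structure()].
#' @param group the age-group name.
#' @return ASMR loss per million of the group's population.
#' @export
cmr_to_asmr <- function(group_cmr_loss, structure, group) {
  stopifnot(inherits(structure, "age_structure"))
  if (!group %in% names(structure$shares)) {
    stop(sprintf("group '%s' not in age structure", group), call. = FALSE)
  }
  group_cmr_loss / structure$shares[[group]]
}

#' Summarize a risk simulation
#'
#' AAL and PML at the requested return periods, per age group and band, on
#' both the CMR scale (per million total population) and the ASMR scale
#' (per million group population), plus the crude all-ages totals (the sum
#' of the group CMR losses, computed on the common event stream).
#'
#' @param result a [simulate_losses()] result.
#' @param return_periods return periods for the PML (default 50 and 100).
#' @return data frame: `group`, `metric` (CMR/ASMR), `band`, `aal`, and one
#'   `pml<T>` column per return period.
#' @export
risk_summary <- function(result, return_periods = c(50, 100)) {
  stopifnot(inherits(result, "risk_result"))
  shares <- result$structure$shares
  rows <- list()
  crude <- 0
  for (g in names(result$annual)) {
    m <- result$annual[[g]]
    crude <- crude + m
    for (b in colnames(m)) {
      losses <- m[, b]
      for (metric in c("CMR", "ASMR")) {
        scl <- if (metric == "ASMR") 1 / shares[[g]] else 1
        r <- data.frame(group = g, metric = metric, band = b,
                        aal = aal(losses) * scl, stringsAsFactors = FALSE)
        for (T in return_periods) {
          r[[sprintf("pml%d", T)]] <- pml(losses, T) * scl
        }
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  for (b in colnames(crude)) {
    losses <- crude[, b]
    r <- data.frame(group = "all", metric = "CMR", band = b,
                    aal = aal(losses), stringsAsFactors = FALSE)
    for (T in return_periods) r[[sprintf("pml%d", T)]] <- pml(losses, T)
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Project future risk under a new climate and age structure
#'
#' Re-detects events on a future daily series using the *historical*
#' resolved threshold (the definition is held fixed; only the climate
#' changes), refits the frequency/intensity hazard on the future period,
#' reruns the Monte Carlo with the unchanged vulnerability curves, and
#' converts losses with the future age structure. Alternatively the future
#' hazard may be given directly as fitted `freq`/`intens` models.
#'
#' @param curves named list of historical `vulnerability_curve`s.
#' @param future_structure the future [age_structure()].
#' @param future_series optional future daily series (data frame with
#'   `date` and temperature columns).
#' @param defn,threshold the historical definition and its resolved
#'   threshold (required with `future_series`).
#' @param freq,intens optional pre-fitted future hazard models (used when
#'   `future_series` is `NULL`).
#' @param period optional `c(first, last)` year for the frequency fit;
#'   defaults to the future series' span.
#' @param n_years,seed Monte Carlo settings.
#' @return list with `risk` (a `risk_result`), `freq`, `intens`,
#'   `mean_hwii`, and `annual_frequency`.
#' @export
project_future <- function(curves, future_structure, future_series = NULL,
                           defn = NULL, threshold = NULL,
                           freq = NULL, intens = NULL, period = NULL,
                           n_years = 10000L, seed = 1L) {
  mean_hwii <- NA_real_
  if (!is.null(future_series)) {
    stopifnot(inherits(defn, "hw_definition"), is.numeric(threshold))
    ev <- detect_events(future_series, defn, threshold = threshold)
    yrs <- as.integer(format(range(as.Date(future_series$date)), "%Y"))
    period <- period %||% yrs
    st <- annual_stats(ev, period)
    freq <- fit_poisson(st$annual$frequency)
    intens <- fit_gamma(st$intensities)
    mean_hwii <- mean(st$intensities)
  } else if (is.null(freq) || is.null(intens)) {
    stop("supply either 'future_series' or both 'freq' and 'intens'",
         call. = FALSE)
  }
  risk <- simulate_losses(freq, intens, curves, future_structure,
                          n_years = n_years, seed = seed)
  list(risk = risk, freq = freq, intens = intens, mean_hwii = mean_hwii,
       annual_frequency = freq$lambda)
}
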