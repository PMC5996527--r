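---
title: "Heat-wave mortality risk: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat-wave mortality risk: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatrisk)
```

## The problem

Heat waves kill, and they kill unevenly: the burden falls mostly on people
aged 65 and over, and it depends on how hot, how long, and how acclimatized
the local population is. `heatrisk` implements an event-based probabilistic
framework for quantifying that burden from two routine data sources — a daily
weather-station series and daily non-accidental death counts by age group —
and for projecting it under a warmer climate and an older population.

The pipeline has four stages:

1. **Detection.** A heat-wave *definition* is a temperature metric (daily
   mean/max/min), a threshold (absolute degrees Celsius or a percentile of the
   reference series), and a minimum duration. Events are maximal runs of
   consecutive days strictly above the threshold, at least the minimum
   duration long. Each event is quantified by the **heat wave intensity
   index** (HWII): the sum over the event's days of the metric's exceedance
   above the threshold, in degree-days. HWII reflects both how hot and how
   long an event was, unlike duration-only or peak-only indices.
2. **Vulnerability.** A distributed lag non-linear model (DLNM) regresses the
   daily crude mortality rate of each age group on a natural-cubic-spline
   cross-basis in (HWII, lag), with confounder adjustment. The local heat-wave
   definition is chosen from a 16-entry catalogue by minimum AIC. The result
   is a cumulative (lag 0–3) HWII–mortality **vulnerability curve** per age
   group, centered at the minimum-mortality HWII, with 95% pointwise bands.
3. **Hazard.** Annual event frequency is modelled as Poisson, event intensity
   (HWII) as Gamma, both checked by a chi-square goodness-of-fit test with
   equal-probability bins.
4. **Risk.** A Monte Carlo simulation (10,000 years by default) draws yearly
   event counts and intensities, pushes each event through the vulnerability
   curves, and accumulates annual losses. Outputs are the loss exceedance
   probability (EP) curve, the average annual loss (AAL), and the probable
   maximum loss (PML) at chosen return periods, per age group and per
   lower/central/upper curve band, in deaths per million per year.

## The regression model

For one age group, the daily outcome is the crude mortality rate
`Yr_t = deaths_t / population` (group deaths over the *total* resident
population, per person-day). The model is ordinary least squares:

```
Yr_t = a + cb(HWII_t, lag) + b1*Tmean_t + b2*Rh_t + b3*Time_t
       + b4*Dow_t + b5*Holiday_t + e_t
```

`HWII_t` is the daily exposure series: on event days it carries the covering
event's *total* HWII, otherwise 0. The cross-basis `cb` is the tensor product
of a natural cubic spline in the exposure (default 2 df; interior knots at
equally spaced quantiles of the positive, i.e. event-day, HWII values;
boundary knots at the observed range) and a lag basis over lags 0–3 (default
3 df). The lag basis contains a constant column plus natural-spline columns
knotted equally over the integer lag range; the constant column is required
so that lag profiles with a uniform component are representable, and it makes
a 1-df lag basis reduce to a plain moving sum. The exposure basis is
evaluated relative to the *center* — the minimum-mortality HWII — so the
fitted association is exactly zero there.

Fitting is Gaussian OLS on rates (identity link), not a count model: the
linear-on-rates formulation is the analysis this package implements and
tests, while the synthetic generator deliberately produces Poisson *counts*,
because counts are what surveillance systems record. The mismatch is part of
what the calibration tests exercise.

Choices a user should know:

* **Centering** is data-driven: the model is fitted once (centered at 0), the
  cumulative curve is scanned over a 101-point grid spanning the observed
  HWII range, and the model is re-fitted once about the argmin (leftmost on
  ties). `fit_vulnerability()` wraps this.
* **AIC** is the Gaussian convention `n log(RSS/n) + 2(k+1)` with constants
  dropped. Comparisons across catalogue definitions are valid because every
  model sees identical observations: the first `max_lag` days (incomplete lag
  window) are dropped from *all* fits.
* **Time** enters as a single linear term. Seasonal mortality confounding is
  otherwise absorbed by the daily mean temperature term; the model formula is
  kept deliberately minimal, and within-year mortality seasonality is exposed
  in the generator as a knob (`mort_seasonal_amplitude`, default 0) rather
  than asserted.
* **Day-of-week** uses Monday as the reference category; holidays are a fixed
  binary calendar (`is_holiday()`), shared between the generator and the
  design matrix.
* The OLS covariance uses the unbiased residual variance `RSS/(n-k)`.
* `sensitivity_sweep()` crosses exposure df {2,3,4}, lag df {3,4,5}, maximum
  lag {3,5,7,10}, and confounder add-ons {none, API, Tmax, Tmin}. Add-ons that
  are exactly collinear with existing columns — on synthetic data Tmax and
  Tmin are, since the generator builds them as `tmean ± diurnal_half_range` —
  are recorded as non-fittable rows rather than silently dropped; a
  rank-deficient design in a direct `fit_dlnm()` call is an error naming the
  collinear columns.

## The definition catalogue

The packaged catalogue (`hw_catalogue()`) holds 16 definitions: daily mean
temperature at the 92.5/95/97.5/98th percentiles and daily maximum
temperature at the 92.5/95/97.5th percentiles or an absolute 35 °C, each
with minimum durations of 2 or 3 days. "Over N consecutive days" is read as
duration ≥ N, and exceedance is strict (`>`); both conventions are flags.
Percentile thresholds are empirical quantiles (linear interpolation) over
the full series passed as the reference period — the reference period is an
explicit modelling input, not a hidden default. Events are assigned to the
calendar year of their start day, so annual frequencies are unambiguous;
missing weather days are a hard error (silent gaps corrupt run detection).

## Hazard and risk

The Poisson rate is the mean of annual event counts, *including* zero-count
years — the reference period defines the denominator. The Gamma fit is
maximum likelihood: Newton iteration on the digamma score equation from a
method-of-moments start (`mean^2/var`, `var/mean`); the scale is
`mean/shape`. Method of moments is available behind a flag for comparison.
The chi-square test uses equal-probability bins under the fitted model
(integer-aware for the Poisson), merged until every expected count is at
least 5, with `bins - 1 - (number of fitted parameters)` degrees of freedom.

The Monte Carlo draws, per simulated year, a Poisson number of events and
i.i.d. Gamma intensities. Each event contributes the cumulative curve value
at its HWII, **once per event**: the hazard model describes frequency and
intensity only, not duration, so losses are not multiplied by event length.
This is the key modelling convention of the risk stage. Curve evaluation is
linear interpolation on the curve grid with linear extrapolation beyond it
(consistent with the natural spline being linear outside its boundary
knots), floored at zero — the curve is centered at the minimum-mortality
HWII, so negative values are sampling noise, not protection. The
lower/central/upper bands are run on a common event stream, so band ordering
holds year by year and the crude loss decomposes exactly over age groups:
`crude AAL = sum_g share_g * ASMR-AAL_g`. Hazard-parameter uncertainty is
*not* propagated into the bands; they reflect the vulnerability-curve CI
envelope only.

PML at return period T is the smallest simulated loss whose exceedance
probability is at most 1/T (the lower-limit convention, i.e. the empirical
1 − 1/T quantile). CMR losses count group deaths against the total
population; ASMR losses divide by the group's population share.

Future projection holds the historical definition and its *resolved*
threshold fixed, re-detects events on a future series, refits the hazard,
reruns the Monte Carlo with unchanged vulnerability curves (no
acclimatization), and converts with the future age structure (default elder
share 0.3153). Supplying fitted future hazard parameters directly is also
supported.

## The synthetic-data generator

Real surveillance and station data are not redistributable, so the package
ships a generator whose defaults describe a single temperate urban area and
whose ground truth is known exactly:

* **Temperature**: a sinusoid peaking in mid-July (annual mean 17 °C,
  half-range 12 °C) plus AR(1) noise (coefficient 0.6, marginal sd 2 °C) plus
  explicitly injected hot spells — Poisson-count per year (default 2/year),
  uniform starts in June–August, geometric durations (mean 4 days), +6 °C
  while active. Spells are injected rather than emergent so the truth event
  calendar is exactly known, which is what makes parameter-recovery tests
  possible. `tmax`/`tmin` are `tmean ± 4 °C`. Leap days are included.
* **Mortality**: Poisson counts with rate `baseline × dow × holiday × trend ×
  seasonality + distributed-lag excess`. Baseline rates (3.4e-6 and 1.4e-4
  deaths per person-day for ages 0–64 and 65+, population 650,000, elder
  share 0.1) give a few deaths per day per group, the magnitude seen in
  city-level surveillance. The excess is a chosen truth function of the
  covering event's HWII (linear, quadratic, hockey-stick, U-shaped, or null),
  spread over lags 0–3 by weights (0.4, 0.3, 0.2, 0.1) summing to 1. Default
  truth slopes are 1e-7 (0–64) and 2e-6 (65+) per degree-day: the elder
  excess is larger by construction, so the elder-dominance pattern is a
  property of the simulated world, reproduced — not asserted — downstream.
* **Confounders**: mild weekend (+2%) and holiday (+5%) effects, +0.5%/year
  trend, Gaussian humidity (75 ± 12%, clipped to [0, 100]), Gamma-shaped air
  pollution index (mean 60, sd 20) independent of temperature.

Every stochastic function takes an explicit seed and restores the caller's
RNG state; identical (config, seed) gives identical datasets to the byte.

What the generator does **not** emulate: spatial correlation between areas,
cause-of-death structure, mortality harvesting (short-term displacement
after events), climate-model bias structure, or realistic air-pollution
dependence on weather. Passing tests on synthetic data therefore demonstrate
the estimators' internal correctness and calibration, not that any real
city's risk equals these numbers.

## Numerical and testing choices

* Problem sizes: the packaged demonstration uses a 45-year record (matching
  the length of a typical station archive) for hazard fitting and definition
  selection, and a 10,000-year Monte Carlo. Calibration studies in the test
  suite use 200 five-year null datasets; recovery studies use 20-year
  records; definition-selection consistency uses 50 replicates of a 20-year
  record with a strong (5e-6 per degree-day) elder slope, a regime chosen to
  test identifiability rather than borderline power.
* The Gamma Newton solver is bounded at 100 iterations (tolerance 1e-10 on
  the score) with step halving to stay in the parameter space; numerically
  constant intensities return a large-shape model with the mean preserved.
* Ties in AIC selection break in catalogue order; ties in centering take the
  leftmost grid point.
* The goodness-of-fit binning merges toward the smaller neighbour and
  guards the expected-count threshold with a 1e-9 float tolerance.
* Known limitations: Gaussian OLS on rates is heteroscedastic under the
  Poisson data-generating process (the tests show its CIs remain usably
  calibrated, covering zero at well over 90% of grid points under the null);
  chi-square calibration with estimated parameters is approximate
  (Chernoff–Lehmann); the percentile axis and knot placement depend on the
  observed event set and so differ across areas by construction; and with a
  deterministic diurnal range the Tmax/Tmin sensitivity add-ons are
  structurally collinear on synthetic data.

## A worked run

```{r demo, eval = FALSE}
cfg <- system.file("extdata", "demo_config.yaml", package = "heatrisk")
res <- run_all(cfg, out_dir = "demo-run", seed = 42)
cat(res$log, sep = "\n")
```

The run writes, per stage: the simulated data and truth sidecar, the
16-definition AIC table and the winner's events, per-age-group fit and curve
files, the hazard fit with its goodness-of-fit table, the risk summary (AAL
and PML at 50/100 years, per band and metric), the EP curve, the projection,
and a markdown report. Rerunning the same configuration and seed reproduces
every output byte for byte.
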