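# heatrisk

Event-based probabilistic assessment of heat-wave mortality risk from daily
weather and mortality surveillance series.

Heat waves are prolonged periods of excessive heat whose mortality burden
depends on intensity, duration, and the local population's acclimatization —
and falls mostly on people aged 65 and over. `heatrisk` is for
epidemiologists and risk analysts who want to go from two routine inputs (a
daily temperature series and daily non-accidental death counts by age group)
to a quantified, probabilistic statement of annual mortality risk, including
projections under a warmer climate and an older population.

## What it computes

**Heat-wave intensity.** A heat-wave definition is a temperature metric
(daily mean/max/min), a threshold (absolute °C or a percentile of the
reference series), and a minimum consecutive-day duration. Each detected
event is quantified by the heat wave intensity index, in degree-days:

    HWII = Σ_{t=1..dur} (Tmetric_t − thr)

**Vulnerability.** For each age group g, a distributed lag non-linear model
(DLNM) regresses the daily crude mortality rate on a natural-cubic-spline
cross-basis in (HWII, lag) plus confounders:

    Yr_t = α + cb(HWII_t, lag) + β₁ Tmean_t + β₂ Rh_t + β₃ Time_t
           + β₄ Dow_t + β₅ Holiday_t + ε_t

with 2 df for the HWII space, 3 df for the lag space, a maximum lag of 3
days, and centering at the minimum-mortality HWII. The local heat-wave
definition is selected from a 16-entry catalogue by minimum AIC. The output
is the cumulative (lag 0–3) HWII–mortality vulnerability curve with 95%
bands.

**Hazard and risk.** Annual event frequency is fitted as Poisson(λ), event
intensity as Gamma(shape, scale), both checked by a chi-square test with
equal-probability bins. A Monte Carlo simulation (10,000 years) of
frequency–severity event streams through the vulnerability curves yields the
loss exceedance probability (EP) curve, the average annual loss (AAL), and
the probable maximum loss (PML) at given return periods — in deaths per
million per year, on both the crude (CMR) and age-specific (ASMR) scales.

Because real mortality surveillance data are not redistributable, the
package includes a synthetic-data generator with known ground truth
(injected hot spells, chosen vulnerability functions, lag weights), which is
what the test suite uses to verify detection, recovery, calibration, and the
analytic compound-Poisson–Gamma limits of the risk stage.

## A worked example

```r
library(heatrisk)
cfg <- system.file("extdata", "demo_config.yaml", package = "heatrisk")
res <- run_all(cfg, out_dir = "demo-run", seed = 42)
cat(res$log, sep = "\n")
```

```
data: simulated 45 years (16436 records), seed 42
select: 16/16 definitions fittable; winner hw03 (164 events, AIC -397983.26)
vulnerability[0-64]: center 0, AIC -426177.88
vulnerability[65+]: center 0, AIC -401312.39
hazard: lambda 3.644/yr, Gamma(shape 0.907, scale 10.947); GOF p = 0.0607 / 0.00166
risk[0-64]: CMR AAL 4.199, ASMR AAL 4.666 per million
risk[65+]: CMR AAL 8.56, ASMR AAL 85.6 per million
project: lambda 8.378/yr, mean HWII 18.57; elder ASMR AAL 114.3 per million
```

Reading this: on the simulated 45-year record the minimum-AIC definition is
`hw03` (daily mean temperature above its 95th percentile for ≥ 2 days),
giving 164 events (λ = 3.64 per year) whose intensities fit a
Gamma(0.91, 10.9 °C·days). Pushing 10,000 simulated years of such events
through the fitted vulnerability curves, residents aged 65+ lose on average
85.6 per million group population per year (central band), versus 4.7 per
million for ages 0–64; the corresponding 1-in-100-year PML is 279 per
million. Under a +3 °C, doubled-spell-rate future with the elder population
share grown to 31.53%, the elder ASMR AAL rises to 114 per million. Events,
AIC table, fits, curves, hazard, risk summary, EP curve, projection, and a
run report are written to `demo-run/`; rerunning with the same seed
reproduces them byte for byte.

The stages are also available as functions — `generate_dataset()`,
`detect_events()`, `select_definition()`, `fit_vulnerability()`,
`fit_poisson()`/`fit_gamma()`/`gof_chisq()`, `simulate_losses()`,
`risk_summary()`, `project_future()` — and a thin CLI wrapper lives at
`inst/cli/run-all.R`. See the methods vignette
(`vignettes/heatrisk-methods.Rmd`) for the model, parameter, and design
details.

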