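# Shared simulation settings for fast tests: a short record with the default
# climate, a stronger elder vulnerability so fits have signal at small n.
quick_cfg <- function(n_years = 5L, seed = 11L, ...) {
  sim_config(n_years = n_years, seed = seed, ...)
}

# A small synthetic series for detection tests: random-walk-ish temperatures.
random_temp_series <- function(n, seed, lo = 20, hi = 40) {
  set.seed(seed)
  data.frame(
    date = seq(as.Date("2001-06-01"), by = "day", length.out = n),
    tmean = runif(n, lo, hi)
  )
}
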