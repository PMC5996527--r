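test_that("ns_basis satisfies the natural-spline defining properties", {
  x <- seq(0, 10, by = 0.01)
  b <- ns_basis(x, df = 3)
  kn <- attr(b, "knots")
  bk <- attr(b, "boundary_knots")

  # second derivative 0 beyond the boundary knots (exactly linear there)
  d2 <- function(x0, h) (ns_at(x0 + h, kn, bk) - 2 * ns_at(x0, kn, bk) +
                           ns_at(x0 - h, kn, bk)) / h^2
  for (x0 in c(bk[1] - 1, bk[2] + 2)) {
    expect_true(all(abs(d2(x0, 0.1)) < 1e-8))
  }
  # natural condition at the boundary knots: the centered second difference
  # vanishes as h -> 0 (it is O(h) there, so shrinking h tenfold must shrink
  # it accordingly)
  for (x0 in bk) {
    coarse <- d2(x0, 1e-2)
    fine <- d2(x0, 1e-3)
    expect_true(all(abs(fine) < pmax(0.2 * abs(coarse), 1e-6)))
  }
  # linear beyond the boundary: equal first differences
  f1 <- ns_at(bk[2] + 1, kn, bk) - ns_at(bk[2] + 0.5, kn, bk)
  f2 <- ns_at(bk[2] + 1.5, kn, bk) - ns_at(bk[2] + 1, kn, bk)
  expect_equal(f1, f2, tolerance = 1e-8)

  # continuity across interior knots
  for (k in kn) {
    expect_true(all(abs(ns_at(k + 1e-9, kn, bk) - ns_at(k - 1e-9, kn, bk))
                    < 1e-7))
  }
  expect_error(ns_basis(x, knots = c(3, 3, 5)), "knots")
})

test_that("regression on ns_basis reproduces a natural cubic spline exactly", {
  # a function that IS a natural cubic spline on these knots: the natural
  # interpolating spline through random values (independent code path)
  set.seed(42)
  kx <- c(0, 2.5, 5, 7.5, 10)
  ky <- rnorm(5)
  f <- stats::splinefun(kx, ky, method = "natural")
  x <- seq(-2, 12, by = 0.05)  # includes extrapolation region
  b <- ns_basis(x, knots = kx[2:4], boundary_knots = c(0, 10))
  fit <- stats::lm.fit(cbind(1, b), f(x))
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("cross-basis: zero series with center 0 gives a zero matrix", {
  spec <- crossbasis_spec(df_var = 2, df_lag = 3, max_lag = 3,
                          var_knots = 5, var_boundary = c(0, 10))
  q <- build_crossbasis(rep(0, 50), spec)
  expect_true(all(q[!attr(q, "incomplete"), ] == 0))
  expect_identical(sum(attr(q, "incomplete")), 3L)
})

test_that("a constant lag basis reduces the cross-basis to a moving sum", {
  set.seed(7)
  hwii <- c(rep(0, 10), rgamma(40, 2, 0.3))
  spec <- crossbasis_spec(df_var = 2, df_lag = 1, max_lag = 3,
                          var_knots = 5, var_boundary = c(0, max(hwii)))
  q <- build_crossbasis(hwii, spec)
  bv <- ns_basis(hwii, knots = 5, boundary_knots = c(0, max(hwii)))
  ok <- !attr(q, "incomplete")
  for (j in 1:2) {
    ms <- bv[, j] + c(0, bv[-length(hwii), j]) +
      c(0, 0, bv[seq_len(length(hwii) - 2), j]) +
      c(0, 0, 0, bv[seq_len(length(hwii) - 3), j])
    expect_equal(q[ok, j], ms[ok], tolerance = 1e-12)
  }
})

test_that("cross-basis equals the naive triple-loop construction", {
  set.seed(1)
  for (rep in 1:5) {
    hwii <- ifelse(runif(80) < 0.7, 0, rgamma(80, 2, 0.25))
    if (all(hwii == 0)) hwii[40] <- 5
    spec <- crossbasis_spec(df_var = sample(2:3, 1), df_lag = sample(2:3, 1),
                            max_lag = sample(2:4, 1))
    q <- build_crossbasis(hwii, spec)
    ok <- !attr(q, "incomplete")
    or <- oracle_crossbasis(hwii, attr(q, "spec"))
    expect_equal(unname(q[ok, ]), or, tolerance = 1e-10)
  }
})

test_that("center outside the observed range is an error", {
  spec <- crossbasis_spec(center = 50, var_knots = 5, var_boundary = c(0, 10))
  expect_error(build_crossbasis(c(rep(0, 20), 5, 8), spec), "center")
})

test_that("the Gaussian AIC follows n log(RSS/n) + 2(k+1)", {
  cfg <- quick_cfg(n_years = 3L)
  ds <- generate_dataset(cfg)
  hwii <- daily_hwii_series(ds$records, ds$truth$events)
  f <- fit_dlnm(ds$records, hwii, crossbasis_spec(), age_group = "65+")
  expect_equal(f$aic, f$n_obs * log(f$rss / f$n_obs) + 2 * (f$k + 1),
               tolerance = 1e-12)
  expect_identical(f$n_obs, nrow(ds$records) - 3L)
})

test_that("AIC is invariant to affine rescaling of a confounder", {
  cfg <- quick_cfg(n_years = 3L)
  ds <- generate_dataset(cfg)
  hwii <- daily_hwii_series(ds$records, ds$truth$events)
  f1 <- fit_dlnm(ds$records, hwii, crossbasis_spec(), age_group = "65+")
  d2 <- ds$records
  d2$rh <- 1000 * d2$rh - 777
  f2 <- fit_dlnm(d2, hwii, crossbasis_spec(), age_group = "65+")
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("a rank-deficient design raises an error naming the columns", {
  cfg <- quick_cfg(n_years = 2L)
  ds <- generate_dataset(cfg)
  hwii <- daily_hwii_series(ds$records, ds$truth$events)
  # tmax = tmean + constant diurnal range: collinear with tmean + intercept
  expect_error(
    fit_dlnm(ds$records, hwii, crossbasis_spec(), age_group = "65+",
             extra_confounders = "tmax"),
    "collinear.*tmax")
})

test_that("confounder coefficients are recovered on confounder-only data", {
  cfg <- quick_cfg(n_years = 20L, seed = 21L,
                   vuln_truth = list("0-64" = vuln_null(),
                                     "65+" = vuln_null()),
                   dow_effects = c(1, 1, 1, 1, 1, 1.1, 1.1),
                   holiday_effect = 1.2, trend_slope = 0)
  ds <- generate_dataset(cfg)
  hwii <- daily_hwii_series(ds$records, ds$truth$events)
  f <- fit_dlnm(ds$records, hwii, crossbasis_spec(), age_group = "65+")
  base <- cfg$baseline_rate[["65+"]] * cfg$age_shares[["65+"]]
  # weekend uplift: +10% of the baseline CMR on Saturdays (dow6)
  est <- f$coef[["dow6"]]
  se <- sqrt(f$vcov["dow6", "dow6"])
  expect_lt(abs(est - 0.1 * base), 3 * se)
  est_h <- f$coef[["holiday"]]
  se_h <- sqrt(f$vcov["holiday", "holiday"])
  expect_lt(abs(est_h - 0.2 * base), 3 * se_h)
})

test_that("cumulative predictions match the naive loop oracle", {
  cfg <- quick_cfg(n_years = 4L)
  ds <- generate_dataset(cfg)
  hwii <- daily_hwii_series(ds$records, ds$truth$events)
  f <- fit_dlnm(ds$records, hwii, crossbasis_spec(), age_group = "65+")
  grid <- seq(0, max(hwii), length.out = 17)
  cc <- cumulative_curve(f, grid)
  expect_equal(cc$central, oracle_cumulative(f, grid), tolerance = 1e-10)
})

test_that("the cumulative curve is zero with ordered bands at the center", {
  cfg <- quick_cfg(n_years = 4L)
  ds <- generate_dataset(cfg)
  hwii <- daily_hwii_series(ds$records, ds$truth$events)
  v <- fit_vulnerability(ds$records, hwii, crossbasis_spec(),
                         age_group = "65+")
  cc <- v$curve
  at_center <- which.min(abs(cc$hwii - attr(cc, "center")))
  expect_equal(cc$central[at_center], 0, tolerance = 1e-12)
  expect_equal(cc$lower95[at_center], 0, tolerance = 1e-12)
  expect_true(all(cc$lower95 <= cc$central + 1e-12))
  expect_true(all(cc$central <= cc$upper95 + 1e-12))
})

test_that("find_center locates the minimum-mortality HWII", {
  cfg <- quick_cfg(n_years = 10L, seed = 31L,
                   vuln_truth = list("0-64" = vuln_null(),
                                     "65+" = vuln_linear(5e-6)))
  ds <- generate_dataset(cfg)
  hwii <- daily_hwii_series(ds$records, ds$truth$events)
  f <- fit_dlnm(ds$records, hwii, crossbasis_spec(), age_group = "65+")

  # a strictly monotone-increasing cumulative curve: center at the grid
  # minimum (coefficients chosen to make the curve the projection of x)
  grid0 <- seq(0, max(hwii), length.out = 101)
  w <- heatrisk:::cumul_weights(f, grid0)
  f_mono <- f
  co <- stats::lm.fit(w, grid0 - grid0[1])$coefficients
  co[is.na(co)] <- 0  # aliased columns of the rank-df_var weight matrix
  f_mono$coef[f_mono$cb_idx] <- co
  cc <- cumulative_curve(f_mono, grid0)
  expect_false(is.unsorted(cc$central))
  expect_equal(find_center(f_mono, grid0), grid0[1])

  # U-shaped truth with a huge population (negligible count noise):
  # center recovered at the known trough up to grid resolution
  trough <- 8
  cfgU <- quick_cfg(n_years = 20L, seed = 32L, population = 1e9,
                    vuln_truth = list("0-64" = vuln_null(),
                                      "65+" = vuln_ushape(2e-6, trough)),
                    dow_effects = rep(1, 7), holiday_effect = 1,
                    trend_slope = 0)
  dsU <- generate_dataset(cfgU)
  hU <- daily_hwii_series(dsU$records, dsU$truth$events)
  fU <- fit_dlnm(dsU$records, hU, crossbasis_spec(df_var = 5),
                 age_group = "65+")
  grid <- seq(0, max(hU), length.out = 101)
  ctr <- find_center(fU, grid)
  expect_lt(abs(ctr - trough), 1.5)  # within spline resolution of the trough

  # flat curve: leftmost argmin
  fit_flat <- fU
  fit_flat$coef[fit_flat$cb_idx] <- 0
  expect_identical(find_center(fit_flat, grid), grid[1])
})

test_that("definition selection returns a singleton catalogue unchanged", {
  cfg <- quick_cfg(n_years = 3L)
  ds <- generate_dataset(cfg)
  one <- list(hw_definition("only", "mean", "percentile", 95, 2))
  sel <- select_definition(ds$records, one, crossbasis_spec())
  expect_identical(sel$best$id, "only")
  expect_identical(nrow(sel$table), 1L)
})

test_that("AIC ties break deterministically in catalogue order", {
  cfg <- quick_cfg(n_years = 3L)
  ds <- generate_dataset(cfg)
  # identical definitions under two ids: identical AIC, first one wins
  two <- list(hw_definition("first", "mean", "percentile", 95, 2),
              hw_definition("second", "mean", "percentile", 95, 2))
  sel <- select_definition(ds$records, two, crossbasis_spec())
  expect_identical(sel$best$id, "first")
  expect_equal(sel$table$aic[1], sel$table$aic[2], tolerance = 1e-12)
})

test_that("zero-event definitions are recorded as non-fittable", {
  cfg <- quick_cfg(n_years = 3L)
  ds <- generate_dataset(cfg)
  cat2 <- list(hw_definition("never", "mean", "absolute", 99, 2),
               hw_definition("ok", "mean", "percentile", 95, 2))
  sel <- select_definition(ds$records, cat2, crossbasis_spec())
  expect_false(sel$table$fittable[1])
  expect_identical(sel$table$n_events[1], 0L)
  expect_identical(sel$best$id, "ok")
})

test_that("sensitivity sweep emits the full grid; singleton equals fit_dlnm", {
  cfg <- quick_cfg(n_years = 4L)
  ds <- generate_dataset(cfg)
  hwii <- daily_hwii_series(ds$records, ds$truth$events)

  one <- sensitivity_sweep(ds$records, hwii, age_group = "65+",
                           df_var = 2, df_lag = 3, max_lag = 3,
                           addons = "none")
  expect_identical(nrow(one), 1L)
  f <- fit_dlnm(ds$records, hwii, crossbasis_spec(), age_group = "65+")
  expect_equal(one$aic, f$aic, tolerance = 1e-12)

  full <- sensitivity_sweep(ds$records, hwii, age_group = "65+",
                            addons = "none")
  expect_identical(nrow(full), 36L)  # 3 df_var x 3 df_lag x 4 max_lag
  expect_true(any(full$fittable))

  # an independent noise confounder barely moves the curve
  withapi <- sensitivity_sweep(ds$records, hwii, age_group = "65+",
                               df_var = 2, df_lag = 3, max_lag = 3,
                               addons = c("none", "api"),
                               return_curves = TRUE)
  curves <- attr(withapi, "curves")
  halfwidth <- (curves[[1]]$upper95 - curves[[1]]$lower95) / 2
  expect_true(all(abs(curves[[1]]$central - curves[[2]]$central)
                  < pmax(halfwidth, 1e-12)))
})

test_that("percentile axis maps order statistics as expected", {
  cc <- vulnerability_curve(hwii = c(1, 2, 3, 4, 5),
                            central = c(0, 1, 2, 3, 4) * 1e-6)
  ev_hwii <- c(1, 2, 3, 4, 5)
  p <- percentile_axis(cc, ev_hwii)
  expect_equal(p$percentile, c(0, 25, 50, 75, 100))
  # monotone map preserves ordering on random inputs
  set.seed(8)
  ev2 <- rgamma(101, 2, 0.3)
  grid <- sort(runif(20, min(ev2), max(ev2)))
  cc2 <- vulnerability_curve(grid, seq_along(grid) * 1e-7)
  p2 <- percentile_axis(cc2, ev2)
  expect_false(is.unsorted(p2$percentile))
  expect_equal(percentile_axis(
    vulnerability_curve(c(median(ev2), max(ev2)), c(0, 1e-6)),
    ev2)$percentile[1], 50)
})

test_that("CI width shrinks like 1/sqrt(n) as the record grows 4x", {
  # hold the basis fixed (explicit knots, fixed evaluation point) so that
  # only the amount of data changes between the two record lengths
  width_at <- function(ny, seed) {
    cfg <- quick_cfg(n_years = ny, seed = seed,
                     vuln_truth = list("0-64" = vuln_null(),
                                       "65+" = vuln_linear(2e-6)))
    ds <- generate_dataset(cfg)
    h <- daily_hwii_series(ds$records, ds$truth$events)
    spec <- crossbasis_spec(var_knots = 8, var_boundary = c(0, 80))
    f <- fit_dlnm(ds$records, h, spec, age_group = "65+")
    cc <- cumulative_curve(f, c(0, 15))
    cc$upper95[2] - cc$lower95[2]
  }
  # average over seeds to tame the per-fit noise in sigma-hat
  w1 <- mean(vapply(1:8, function(s) width_at(8L, s), numeric(1)))
  w4 <- mean(vapply(1:8, function(s) width_at(32L, s), numeric(1)))
  expect_gt(w1 / w4, 2 * 0.75)
  expect_lt(w1 / w4, 2 * 1.25)
})

test_that("hockey-stick truth is recovered more closely as years grow", {
  mad_at <- function(ny) {
    cfg <- quick_cfg(n_years = ny, seed = 91L,
                     vuln_truth = list(
                       "0-64" = vuln_null(),
                       "65+" = vuln_hockey(4e-6, breakpoint = 8)),
                     dow_effects = rep(1, 7), holiday_effect = 1,
                     trend_slope = 0)
    ds <- generate_dataset(cfg)
    h <- daily_hwii_series(ds$records, ds$truth$events)
    f <- fit_dlnm(ds$records, h, crossbasis_spec(df_var = 3),
                  age_group = "65+")
    grid <- seq(0, max(h), length.out = 40)
    cc <- cumulative_curve(f, grid)
    truth <- cfg$age_shares[["65+"]] *
      eval_vuln(cfg$vuln_truth[["65+"]], grid)
    mean(abs(cc$central - truth))
  }
  m_small <- mad_at(6L)
  m_big <- mad_at(48L)
  expect_lt(m_big, m_small)
})
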