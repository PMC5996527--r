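# Distributed lag non-linear model: natural cubic spline cross-basis,
# Gaussian OLS fit on crude mortality rates, AIC-based definition selection,
# and centered cumulative vulnerability curves.

#' Natural cubic spline basis
#'
#' Thin wrapper around [splines::ns()] exposing the package's knot
#' conventions: `df` is the basis dimension (number of columns, intercept
#' excluded); with `df` given and no knots, interior knots sit at equally
#' spaced quantiles of `x` and boundary knots at its range. The basis is
#' piecewise cubic, C2-continuous, and linear beyond the boundary knots
#' (natural condition).
#'
#' @param x evaluation points.
#' @param df basis dimension (>= 1).
#' @param knots interior knots (strictly increasing); overrides `df`.
#' @param boundary_knots length-2 boundary knots.
#' @return matrix with `df` columns and attributes `knots`,
#'   `boundary_knots`.
#' @export
ns_basis <- function(x, df = NULL, knots = NULL, boundary_knots = NULL) {
  if (!is.null(knots)) {
    if (anyDuplicated(knots) || is.unsorted(knots, strictly = TRUE)) {
      stop("interior knots must be strictly increasing with no duplicates",
           call. = FALSE)
    }
  } else {
    check_that(!is.null(df) && df >= 1 && df == round(df), "df",
               "must be an integer >= 1")
    if (df > 1) {
      p <- seq_len(df - 1) / df
      knots <- unname(stats::quantile(x, probs = p, type = 7))
      if (anyDuplicated(knots)) {
        stop("quantile-based interior knots are duplicated; supply 'knots'",
             call. = FALSE)
      }
    }
  }
  boundary_knots <- boundary_knots %||% range(x)
  b <- splines::ns(x, knots = knots, Boundary.knots = boundary_knots,
                   intercept = FALSE)
  m <- matrix(as.numeric(b), nrow = length(x))
  attr(m, "knots") <- knots
  attr(m, "boundary_knots") <- boundary_knots
  m
}

#' Cross-basis specification
#'
#' Dimensions and centering of the bi-dimensional (exposure x lag) basis.
#' Both margins are natural cubic splines. `df_var` columns describe the
#' HWII direction (interior knots at equally spaced quantiles of the
#' positive, i.e. event-day, HWII values; boundary knots at the observed
#' range). `df_lag` columns describe the lag direction and *include* a
#' constant (lag-intercept) column, with the remaining spline columns
#' knotted equally over the integer lag range. The exposure basis is
#' evaluated relative to `center`, the HWII at which effects are zero.
#'
#' @param df_var basis dimension for the HWII direction (default 2).
#' @param df_lag basis dimension for the lag direction, constant column
#'   included (default 3).
#' @param max_lag maximum lag in days (default 3).
#' @param center HWII value at which the association is zeroed (default 0);
#'   must lie inside the observed HWII range.
#' @param var_knots,var_boundary optional explicit knots for the HWII basis.
#' @return an object of class `crossbasis_spec`.
#' @export
crossbasis_spec <- function(df_var = 2L, df_lag = 3L, max_lag = 3L,
                            center = 0, var_knots = NULL,
                            var_boundary = NULL) {
  check_that(df_var >= 1 && df_var == round(df_var), "df_var",
             "must be an integer >= 1")
  check_that(df_lag >= 1 && df_lag == round(df_lag), "df_lag",
             "must be an integer >= 1")
  check_that(max_lag >= 0 && max_lag == round(max_lag), "max_lag",
             "must be an integer >= 0")
  if (max_lag == 0 && df_lag > 1) {
    stop("with max_lag = 0 the lag basis must have df_lag = 1", call. = FALSE)
  }
  structure(list(df_var = as.integer(df_var), df_lag = as.integer(df_lag),
                 max_lag = as.integer(max_lag), center = center,
                 var_knots = var_knots, var_boundary = var_boundary),
            class = "crossbasis_spec")
}

# Lag-direction basis: constant column plus a natural spline of the integer
# lags with equally spaced interior knots. Rows = lags 0..max_lag.
lag_basis <- function(spec) {
  lags <- 0:spec$max_lag
  if (spec$df_lag == 1L) {
    return(matrix(1, length(lags), 1))
  }
  kn <- if (spec$df_lag > 2L) {
    seq(0, spec$max_lag, length.out = spec$df_lag)[2:(spec$df_lag - 1L)]
  }
  cbind(1, ns_basis(lags, df = spec$df_lag - 1L, knots = kn,
                    boundary_knots = c(0, spec$max_lag)))
}

# HWII-direction basis with resolved knots, evaluated relative to the center.
var_basis <- function(x, spec) {
  kn <- spec$var_knots
  bk <- spec$var_boundary
  if (is.null(bk)) bk <- range(x)
  if (is.null(kn) && spec$df_var > 1L) {
    pos <- x[x > 0]
    if (length(pos) == 0L) {
      stop("no positive HWII values: cannot place exposure-basis knots",
           call. = FALSE)
    }
    p <- seq_len(spec$df_var - 1L) / spec$df_var
    kn <- unname(stats::quantile(pos, probs = p, type = 7))
    if (anyDuplicated(kn)) {
      stop("duplicated HWII knots; too few distinct event intensities",
           call. = FALSE)
    }
  }
  if (spec$center < bk[1] || spec$center > bk[2]) {
    stop(sprintf("center %g lies outside the observed HWII range [%g, %g]",
                 spec$center, bk[1], bk[2]), call. = FALSE)
  }
  b <- ns_basis(x, knots = kn, boundary_knots = bk)
  b0 <- ns_basis(spec$center, knots = kn, boundary_knots = bk)
  bc <- sweep(b, 2, as.numeric(b0))
  attr(bc, "knots") <- kn
  attr(bc, "boundary_knots") <- bk
  bc
}

#' Build the exposure-lag cross-basis matrix
#'
#' Column (j, l) at day t is `sum_{lag=0..max_lag} Bvar_j(hwii[t-lag]) *
#' Blag_l(lag)`, with the exposure basis centered so that a series constant
#' at the center yields an all-zero matrix. The first `max_lag` rows have an
#' incomplete lag window; they are returned as `NA` and flagged by the
#' logical attribute `"incomplete"` (fits drop them so every model compared
#' sees identical observations).
#'
#' @param hwii daily HWII exposure series (from [daily_hwii_series()]).
#' @param spec a [crossbasis_spec()].
#' @return an `n x (df_var * df_lag)` matrix with attributes `spec` (knots
#'   resolved), `incomplete`, and column names `cb_v<j>l<l>`.
#' @export
build_crossbasis <- function(hwii, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  n <- length(hwii)
  if (n <= spec$max_lag) stop("series shorter than the lag window", call. = FALSE)
  bv <- var_basis(hwii, spec)
  spec$var_knots <- attr(bv, "knots")
  spec$var_boundary <- attr(bv, "boundary_knots")
  bl <- lag_basis(spec)

  q <- matrix(0, n, spec$df_var * spec$df_lag)
  for (lag in 0:spec$max_lag) {
    shifted <- rbind(matrix(NA_real_, lag, spec$df_var),
                     bv[seq_len(n - lag), , drop = FALSE])
    # outer expansion: column (j-1)*df_lag + l accumulates shifted[,j]*bl[lag,l]
    q <- q + shifted[, rep(seq_len(spec$df_var), each = spec$df_lag),
                     drop = FALSE] *
      matrix(rep(bl[lag + 1L, ], spec$df_var), n, ncol(q), byrow = TRUE)
  }
  colnames(q) <- paste0("cb_v", rep(seq_len(spec$df_var), each = spec$df_lag),
                        "l", rep(seq_len(spec$df_lag), spec$df_var))
  incomplete <- seq_len(n) <= spec$max_lag
  attr(q, "spec") <- spec
  attr(q, "incomplete") <- incomplete
  q
}

# Assemble outcome and design matrix for one age group.
dlnm_design <- function(data, hwii, spec, age_group, extra = character()) {
  n <- nrow(data)
  stopifnot(length(hwii) == n)
  deaths <- switch(age_group,
    "0-64" = data$deaths_0_64,
    "65+" = data$deaths_65plus,
    "all" = data$deaths_0_64 + data$deaths_65plus,
    stop(sprintf("unknown age group '%s'", age_group), call. = FALSE)
  )
  y <- crude_rate(deaths, data$population)
  cb <- build_crossbasis(hwii, spec)

  dates <- as.Date(data$date)
  dow <- factor(format(dates, "%u"), levels = as.character(1:7))  # Monday ref
  dow_mm <- stats::model.matrix(~dow)[, -1, drop = FALSE]
  colnames(dow_mm) <- paste0("dow", 2:7)
  x <- cbind(
    `(Intercept)` = 1,
    cb,
    tmean = data$tmean,
    rh = data$rh,
    time = seq_len(n),
    dow_mm,
    holiday = data$holiday
  )
  for (v in extra) {
    if (!v %in% names(data)) {
      stop(sprintf("confounder add-on '%s' not found in data", v),
           call. = FALSE)
    }
    x <- cbind(x, data[[v]])
    colnames(x)[ncol(x)] <- v
  }
  keep <- !attr(cb, "incomplete")
  list(y = y[keep], x = x[keep, , drop = FALSE],
       cb_idx = 1L + seq_len(ncol(cb)),
       spec = attr(cb, "spec"), n_dropped = sum(!keep))
}

#' Fit the distributed-lag linear model for one age group
#'
#' Ordinary least squares of the daily crude mortality rate (group deaths
#' over total population, per person-day) on an intercept, the HWII x lag
#' cross-basis, daily mean temperature, relative humidity, a linear time
#' trend, six day-of-week indicators (Monday reference), a holiday
#' indicator, and any extra confounder columns. Rows with an incomplete lag
#' window are dropped. AIC follows the Gaussian convention
#' `n * log(RSS/n) + 2 * (k + 1)`.
#'
#' @param data daily records (as from [generate_dataset()]'s `records` or
#'   [read_daily_records()]).
#' @param hwii daily HWII exposure series aligned with `data`.
#' @param spec a [crossbasis_spec()].
#' @param age_group `"0-64"`, `"65+"`, or `"all"` (summed groups).
#' @param extra_confounders optional character vector of extra columns
#'   (e.g. `"api"`, `"tmax"`, `"tmin"`).
#' @param definition_id optional label of the heat-wave definition used.
#' @return an object of class `dlnm_fit`: coefficients, covariance
#'   (`sigma^2 (X'X)^{-1}`, `sigma^2 = RSS/(n-k)`), AIC, the resolved
#'   cross-basis spec, and the observed HWII range. A rank-deficient design
#'   is an error naming the collinear columns.
#' @export
fit_dlnm <- function(data, hwii, spec = crossbasis_spec(),
                     age_group = c("65+", "0-64", "all"),
                     extra_confounders = character(),
                     definition_id = NA_character_) {
  age_group <- match.arg(age_group)
  d <- dlnm_design(data, hwii, spec, age_group, extra_confounders)
  x <- d$x
  y <- d$y
  n <- length(y)
  k <- ncol(x)

  qrx <- qr(x)
  if (qrx$rank < k) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1L):k]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  coef <- qr.coef(qrx, y)
  res <- y - x %*% coef
  rss <- sum(res^2)
  sigma2 <- rss / (n - k)
  xtx_inv <- chol2inv(qr.R(qrx)[, order(qrx$pivot), drop = FALSE])
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(x), colnames(x))
  aic <- n * log(rss / n) + 2 * (k + 1)

  structure(
    list(coef = coef, vcov = vcov, sigma2 = sigma2, rss = rss,
         n_obs = n, k = k, aic = aic, cb_idx = d$cb_idx, spec = d$spec,
         age_group = age_group, definition_id = definition_id,
         observed_range = range(hwii), n_dropped = d$n_dropped),
    class = "dlnm_fit"
  )
}

#' @export
print.dlnm_fit <- function(x, ...) {
  cat(sprintf(
    "<dlnm_fit> group %s, definition %s: n = %d, k = %d, AIC = %.2f\n",
    x$age_group, x$definition_id, x$n_obs, x$k, x$aic))
  cat(sprintf("  HWII range [%g, %g], center %g\n",
              x$observed_range[1], x$observed_range[2], x$spec$center))
  invisible(x)
}

#' Select the local heat-wave definition by minimum AIC
#'
#' Fits one DLNM per catalogued definition on identical observations (same
#' outcome, same rows after the common lag-window drop) and returns the
#' definition whose model attains the lowest AIC, with the full AIC table.
#' Definitions yielding no events (or an otherwise unfittable model) are
#' recorded as non-fittable and excluded from the argmin. Ties break in
#' catalogue order.
#'
#' @param data daily records.
#' @param catalogue list of [hw_definition()]s (e.g. [hw_catalogue()]).
#' @param spec a [crossbasis_spec()].
#' @param age_group age group used for selection (default `"all"`).
#' @return list with `best` (the winning definition), `best_fit`, `events`
#'   (the winner's events), and `table` (data frame: `id`, `n_events`,
#'   `threshold`, `aic`, `fittable`).
#' @export
select_definition <- function(data, catalogue, spec = crossbasis_spec(),
                              age_group = "all") {
  rows <- vector("list", length(catalogue))
  fits <- vector("list", length(catalogue))
  evs <- vector("list", length(catalogue))
  for (i in seq_along(catalogue)) {
    defn <- catalogue[[i]]
    thr <- resolve_threshold(data, defn)
    ev <- detect_events(data, defn, threshold = thr)
    aic <- NA_real_
    ok <- FALSE
    if (nrow(ev) > 0L) {
      hwii <- daily_hwii_series(data, ev)
      f <- tryCatch(
        fit_dlnm(data, hwii, spec, age_group = age_group,
                 definition_id = defn$id),
        error = function(e) NULL
      )
      if (!is.null(f)) {
        aic <- f$aic
        ok <- TRUE
        fits[[i]] <- f
        evs[[i]] <- ev
      }
    }
    rows[[i]] <- data.frame(id = defn$id, n_events = nrow(ev),
                            threshold = thr, aic = aic, fittable = ok,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$fittable)) {
    stop("no catalogued definition produced a fittable model", call. = FALSE)
  }
  aics <- ifelse(tab$fittable, tab$aic, Inf)
  best_i <- which.min(aics)  # first minimum: ties break in catalogue order
  list(best = catalogue[[best_i]], best_fit = fits[[best_i]],
       events = evs[[best_i]], table = tab)
}

# Row of cumulative-curve weights at exposure values x: the centered
# exposure basis scaled by the lag basis' column sums over lags 0..max_lag.
cumul_weights <- function(fit, x) {
  spec <- fit$spec
  bv <- ns_basis(x, knots = spec$var_knots,
                 boundary_knots = spec$var_boundary)
  b0 <- ns_basis(spec$center, knots = spec$var_knots,
                 boundary_knots = spec$var_boundary)
  bc <- sweep(bv, 2, as.numeric(b0))
  lsum <- colSums(lag_basis(spec))
  w <- matrix(0, length(x), spec$df_var * spec$df_lag)
  for (j in seq_len(spec$df_var)) {
    cols <- (j - 1L) * spec$df_lag + seq_len(spec$df_lag)
    w[, cols] <- bc[, j] %o% lsum
  }
  w
}

#' Cumulative (lag 0-3) vulnerability curve with 95% CI
#'
#' Sums the fitted exposure-lag surface over the lag window at each grid
#' HWII, relative to the center: the excess crude mortality rate per person
#' accumulated over the `max_lag + 1` days following exposure. Delta-method
#' pointwise 95% confidence bands. The curve passes through 0 at the center
#' exactly.
#'
#' @param fit a [fit_dlnm()] object.
#' @param grid HWII grid; default 50 equally spaced points over the
#'   observed range.
#' @return an object of class `vulnerability_curve` (see
#'   [vulnerability_curve()]).
#' @export
cumulative_curve <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "dlnm_fit"))
  grid <- grid %||% seq(fit$observed_range[1], fit$observed_range[2],
                        length.out = 50)
  w <- cumul_weights(fit, grid)
  beta <- fit$coef[fit$cb_idx]
  sig <- fit$vcov[fit$cb_idx, fit$cb_idx, drop = FALSE]
  central <- as.numeric(w %*% beta)
  se <- sqrt(pmax(0, rowSums((w %*% sig) * w)))
  vulnerability_curve(
    hwii = grid, central = central,
    lower95 = central - 1.96 * se, upper95 = central + 1.96 * se,
    center = fit$spec$center, age_group = fit$age_group,
    observed_range = fit$observed_range, definition_id = fit$definition_id
  )
}

#' Find the minimum-mortality HWII (the centering value)
#'
#' Scans the cumulative curve of an (arbitrarily centered) fit over a grid
#' spanning the observed HWII range and returns the grid value with the
#' lowest cumulative excess mortality; ties take the leftmost point. The
#' usual workflow re-fits once with the returned center
#' (see [fit_vulnerability()]).
#'
#' @param fit a [fit_dlnm()] object.
#' @param grid candidate HWII values; default 101 points over the observed
#'   range.
#' @return the minimizing HWII value.
#' @export
find_center <- function(fit, grid = NULL) {
  grid <- grid %||% seq(fit$observed_range[1], fit$observed_range[2],
                        length.out = 101)
  cc <- cumulative_curve(fit, grid)
  grid[which.min(cc$central)]
}

#' Fit an age group's vulnerability curve with data-driven centering
#'
#' Fits the DLNM at the spec's initial center, locates the
#' minimum-mortality HWII with [find_center()], re-fits once about it, and
#' returns the re-centered fit together with its cumulative curve.
#'
#' @inheritParams fit_dlnm
#' @param grid optional HWII grid for centering and the returned curve.
#' @return list with `fit` (re-centered `dlnm_fit`), `curve`
#'   (`vulnerability_curve`), and `center`.
#' @export
fit_vulnerability <- function(data, hwii, spec = crossbasis_spec(),
                              age_group = "65+",
                              extra_confounders = character(),
                              definition_id = NA_character_, grid = NULL) {
  f0 <- fit_dlnm(data, hwii, spec, age_group, extra_confounders,
                 definition_id)
  ctr <- find_center(f0, grid)
  spec$center <- ctr
  spec$var_knots <- f0$spec$var_knots
  spec$var_boundary <- f0$spec$var_boundary
  f1 <- fit_dlnm(data, hwii, spec, age_group, extra_confounders,
                 definition_id)
  list(fit = f1, curve = cumulative_curve(f1, grid), center = ctr)
}

#' Sensitivity sweep over DLNM hyper-parameters
#'
#' Cartesian sweep over the basis dimensions, the maximum lag, and optional
#' confounder add-ons. Each combination is fitted independently;
#' combinations whose design is rank-deficient (e.g. a lag basis richer
#' than the lag window supports, or an add-on collinear with an existing
#' confounder) are recorded as non-fittable rather than raised.
#'
#' @param data daily records.
#' @param hwii daily HWII exposure series.
#' @param age_group age group to fit.
#' @param df_var,df_lag,max_lag vectors of values to sweep.
#' @param addons confounder add-ons: subset of
#'   `c("none", "api", "tmax", "tmin")`.
#' @param center initial center for all fits.
#' @param return_curves if `TRUE`, attach each fittable combination's
#'   cumulative curve.
#' @return data frame (`df_var`, `df_lag`, `max_lag`, `addon`, `aic`,
#'   `fittable`), with a list of curves as attribute `"curves"` when
#'   requested.
#' @export
sensitivity_sweep <- function(data, hwii, age_group = "65+",
                              df_var = 2:4, df_lag = 3:5,
                              max_lag = c(3L, 5L, 7L, 10L),
                              addons = c("none", "api", "tmax", "tmin"),
                              center = 0, return_curves = FALSE) {
  grid <- expand.grid(df_var = df_var, df_lag = df_lag, max_lag = max_lag,
                      addon = addons, stringsAsFactors = FALSE)
  aic <- rep(NA_real_, nrow(grid))
  ok <- logical(nrow(grid))
  curves <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    extra <- if (grid$addon[i] == "none") character() else grid$addon[i]
    f <- tryCatch({
      sp <- crossbasis_spec(grid$df_var[i], grid$df_lag[i], grid$max_lag[i],
                            center = center)
      fit_dlnm(data, hwii, sp, age_group, extra_confounders = extra)
    }, error = function(e) NULL)
    if (!is.null(f)) {
      aic[i] <- f$aic
      ok[i] <- TRUE
      if (return_curves) curves[[i]] <- cumulative_curve(f)
    }
  }
  out <- cbind(grid, aic = aic, fittable = ok)
  if (return_curves) attr(out, "curves") <- curves
  out
}

#' Re-index a vulnerability curve by area-specific HWII percentile
#'
#' Adds a `percentile` column mapping each grid HWII to its percentile
#' among the observed event intensities (linear interpolation between order
#' statistics; the minimum maps to 0, the median to 50, the maximum to
#' 100). The monotone map preserves the curve's ordering, making curves
#' comparable across areas with different HWII scales.
#'
#' @param curve a `vulnerability_curve`.
#' @param event_hwiis observed per-event HWII values of the area.
#' @return the curve with a `percentile` column.
#' @export
percentile_axis <- function(curve, event_hwiis) {
  stopifnot(inherits(curve, "vulnerability_curve"), length(event_hwiis) >= 1)
  v <- sort(event_hwiis)
  p <- if (length(v) == 1L) {
    ifelse(curve$hwii >= v, 100, 0)
  } else {
    100 * stats::approx(v, seq(0, 1, length.out = length(v)),
                        xout = curve$hwii, rule = 2, ties = "ordered")$y
  }
  curve$percentile <- p
  curve
}
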