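# Independent brute-force oracles used to validate the fast implementations.

# Window-scan event detector: for every candidate start day, walk forward
# while the metric exceeds the threshold; keep maximal runs of at least
# min_duration days and sum exceedances day by day.
oracle_detect <- function(x, dates, thr, min_duration) {
  n <- length(x)
  out <- list()
  for (s in seq_len(n)) {
    if (x[s] > thr && (s == 1L || x[s - 1L] <= thr)) {
      e <- s
      while (e < n && x[e + 1L] > thr) e <- e + 1L
      if (e - s + 1L >= min_duration) {
        hwii <- 0
        for (t in s:e) hwii <- hwii + (x[t] - thr)
        out[[length(out) + 1L]] <- data.frame(
          start = dates[s], end = dates[e], duration = e - s + 1L,
          hwii = hwii)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = as.Date(character()), end = as.Date(character()),
               duration = integer(), hwii = numeric())
}

# Sort-and-interpolate empirical quantile (the type-7 formula from first
# principles).
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# Scalar natural-spline evaluation for the naive cross-basis.
ns_at <- function(x, knots, boundary) {
  as.numeric(splines::ns(x, knots = knots, Boundary.knots = boundary))
}

# Naive cross-basis: explicit loops over day, exposure-basis column, and
# lag-basis column, evaluating the splines point by point. Returns only the
# rows with a complete lag window.
oracle_crossbasis <- function(hwii, spec) {
  kn <- spec$var_knots
  bk <- spec$var_boundary
  lags <- 0:spec$max_lag
  lb <- heatrisk:::lag_basis(spec)
  b0 <- ns_at(spec$center, kn, bk)
  n <- length(hwii)
  rows <- (spec$max_lag + 1L):n
  q <- matrix(0, length(rows), spec$df_var * spec$df_lag)
  for (r in seq_along(rows)) {
    t <- rows[r]
    for (j in seq_len(spec$df_var)) {
      for (l in seq_len(spec$df_lag)) {
        acc <- 0
        for (lag in lags) {
          bj <- ns_at(hwii[t - lag], kn, bk)[j] - b0[j]
          acc <- acc + bj * lb[lag + 1L, l]
        }
        q[r, (j - 1L) * spec$df_lag + l] <- acc
      }
    }
  }
  q
}

# Naive cumulative prediction: explicit sum of the fitted surface over the
# lag window at each grid value, minus its value at the center.
oracle_cumulative <- function(fit, grid) {
  spec <- fit$spec
  kn <- spec$var_knots
  bk <- spec$var_boundary
  lb <- heatrisk:::lag_basis(spec)
  beta <- fit$coef[fit$cb_idx]
  b0 <- ns_at(spec$center, kn, bk)
  vapply(grid, function(x) {
    bx <- ns_at(x, kn, bk)
    acc <- 0
    for (j in seq_len(spec$df_var)) {
      for (l in seq_len(spec$df_lag)) {
        for (lag in 0:spec$max_lag) {
          acc <- acc + (bx[j] - b0[j]) * lb[lag + 1L, l] *
            beta[(j - 1L) * spec$df_lag + l]
        }
      }
    }
    acc
  }, numeric(1))
}

# Exact integral of the empirical exceedance-probability step function.
oracle_ep_integral <- function(losses) {
  ec <- ep_curve(losses)
  xs <- ec$loss
  ep <- ec$ep
  if (xs[1] > 0) {
    xs <- c(0, xs)
    ep <- c(1, ep)
  }
  sum(diff(xs) * ep[-length(ep)])
}

# Asymptotic standard errors of the Gamma MLE (inverse Fisher information).
gamma_mle_se <- function(shape, scale, n) {
  info <- matrix(c(trigamma(shape), 1 / scale,
                   1 / scale, shape / scale^2), 2, 2)
  sqrt(diag(solve(n * info)))
}
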