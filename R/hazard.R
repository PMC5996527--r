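# Hazard model: annual event frequency (Poisson) and event intensity (Gamma),
# with chi-square goodness of fit and frequency-severity sampling.

#' Fit the annual-frequency Poisson model
#'
#' Maximum likelihood: lambda is the arithmetic mean of the annual event
#' counts. Zero-count years are included -- the reference period defines the
#' denominator.
#'
#' @param annual_counts non-negative integer counts, one per year.
#' @return object of class `freq_model` with `lambda` and `n_years`.
#' @export
fit_poisson <- function(annual_counts) {
  check_that(length(annual_counts) >= 1, "annual_counts",
             "needs at least one year")
  check_that(all(annual_counts >= 0) &&
               all(annual_counts == round(annual_counts)),
             "annual_counts", "must be non-negative integers")
  lam <- mean(annual_counts)
  if (lam == 0) warning("all annual counts are zero: degenerate frequency model")
  structure(list(lambda = lam, n_years = length(annual_counts)),
            class = "freq_model")
}

#' Fit the event-intensity Gamma model
#'
#' Default is maximum likelihood: the shape solves the digamma score
#' equation `log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))` by
#' Newton iteration from the method-of-moments start
#' (`mean^2/var`, `var/mean`); the scale is `mean(x)/shape`. The
#' method-of-moments estimate itself is available with `method = "mom"`.
#'
#' @param intensities strictly positive event intensities (HWII,
#'   degree-days); at least 3 values.
#' @param method `"mle"` (default) or `"mom"`.
#' @param max_iter,tol Newton iteration bound and score tolerance.
#' @return object of class `intensity_model` with `shape`, `scale`,
#'   `n_events`, `method`.
#' @export
fit_gamma <- function(intensities, method = c("mle", "mom"),
                      max_iter = 100L, tol = 1e-10) {
  method <- match.arg(method)
  x <- intensities
  check_that(length(x) >= 3, "intensities", "needs at least 3 events")
  check_that(all(is.finite(x)) && all(x > 0), "intensities",
             "must all be strictly positive")
  m <- mean(x)
  v <- stats::var(x)
  shape0 <- if (v > 0) m^2 / v else 1e8
  if (method == "mom") {
    return(structure(list(shape = shape0, scale = if (v > 0) v / m else m / shape0,
                          n_events = length(x), method = "mom",
                          iterations = 0L),
                     class = "intensity_model"))
  }
  s <- log(m) - mean(log(x))
  if (s <= 0) {  # numerically constant data: shape -> large, mean preserved
    return(structure(list(shape = 1e8, scale = m / 1e8, n_events = length(x),
                          method = "mle", iterations = 0L),
                     class = "intensity_model"))
  }
  a <- shape0
  it <- 0L
  repeat {
    f <- log(a) - digamma(a) - s
    if (abs(f) < tol) break
    it <- it + 1L
    if (it > max_iter) {
      stop(sprintf("Gamma MLE did not converge in %d iterations (last shape %g, score %g)",
                   max_iter, a, f), call. = FALSE)
    }
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    while (a_new <= 0) {  # keep the iterate in the parameter space
      step <- step / 2
      a_new <- a - step
    }
    a <- a_new
  }
  structure(list(shape = a, scale = m / a, n_events = length(x),
                 method = "mle", iterations = it),
            class = "intensity_model")
}

#' @export
print.freq_model <- function(x, ...) {
  cat(sprintf("<freq_model> Poisson lambda = %.4g events/year (%d years)\n",
              x$lambda, x$n_years))
  invisible(x)
}

#' @export
print.intensity_model <- function(x, ...) {
  cat(sprintf("<intensity_model> Gamma shape = %.4g, scale = %.4g degC-days (%d events, %s)\n",
              x$shape, x$scale, x$n_events, x$method))
  invisible(x)
}

# Model CDF/quantile dispatch for the two hazard families.
hazard_cdf <- function(model, q) {
  if (inherits(model, "freq_model")) {
    stats::ppois(q, model$lambda)
  } else if (inherits(model, "intensity_model")) {
    stats::pgamma(q, shape = model$shape, scale = model$scale)
  } else stop("unsupported model class")
}

hazard_quantile <- function(model, p) {
  if (inherits(model, "freq_model")) {
    stats::qpois(p, model$lambda)
  } else if (inherits(model, "intensity_model")) {
    stats::qgamma(p, shape = model$shape, scale = model$scale)
  } else stop("unsupported model class")
}

#' Chi-square goodness of fit with equal-probability bins
#'
#' Bins are placed at equal probability under the fitted model (integer-aware
#' for the Poisson), then adjacent bins are merged until every expected
#' count is at least `min_expected`. Pearson statistic with
#' `bins - 1 - n_fitted_params` degrees of freedom; the model passes when
#' `p > alpha`.
#'
#' @param model a `freq_model` or `intensity_model`.
#' @param data the observed sample the model describes.
#' @param alpha significance level (default 0.01).
#' @param min_expected minimum expected count per bin (default 5).
#' @param n_fitted_params number of parameters estimated from `data`;
#'   defaults to 1 (Poisson) or 2 (Gamma). Set 0 when testing an externally
#'   given model.
#' @return object of class `gof_result`: `statistic`, `dof`, `p_value`,
#'   `pass`, and the bin table (`edges`, `observed`, `expected`).
#' @export
gof_chisq <- function(model, data, alpha = 0.01, min_expected = 5,
                      n_fitted_params = NULL) {
  n <- length(data)
  check_that(n >= 1, "data", "is empty")
  npar <- as.integer(n_fitted_params %||%
                       if (inherits(model, "freq_model")) 1L else 2L)

  k0 <- max(3L, min(30L, floor(n / min_expected)))
  discrete <- inherits(model, "freq_model")
  if (discrete) {
    inner <- unique(hazard_quantile(model, seq_len(k0 - 1) / k0)) + 0.5
    edges <- c(-0.5, inner, Inf)
  } else {
    inner <- unique(hazard_quantile(model, seq_len(k0 - 1) / k0))
    edges <- c(-Inf, inner, Inf)
  }
  edges <- unique(edges)
  probs <- diff(hazard_cdf(model, edges))
  # hazard_cdf(-Inf / -0.5) is 0 for both families on their support
  expected <- n * probs
  observed <- as.numeric(table(cut(data, breaks = edges, right = TRUE)))

  # merge any bin with expected < min_expected into its smaller neighbour
  # (tolerance guards against float-boundary re-merging)
  min_expected <- min_expected - 1e-9
  while (length(expected) > 1L && any(expected < min_expected)) {
    i <- which.min(expected)
    j <- if (i == 1L) 2L else if (i == length(expected)) i - 1L else
      if (expected[i - 1L] <= expected[i + 1L]) i - 1L else i + 1L
    lo <- min(i, j); hi <- max(i, j)
    expected[lo] <- expected[lo] + expected[hi]
    observed[lo] <- observed[lo] + observed[hi]
    expected <- expected[-hi]
    observed <- observed[-hi]
    edges <- edges[-hi]
  }
  nb <- length(expected)
  dof <- nb - 1L - npar
  if (dof < 1L) {
    stop("too few bins after merging to test the fitted model", call. = FALSE)
  }
  stat <- sum((observed - expected)^2 / expected)
  p <- stats::pchisq(stat, dof, lower.tail = FALSE)
  structure(
    list(statistic = stat, dof = dof, p_value = p, pass = p > alpha,
         alpha = alpha,
         bins = data.frame(
           lower = edges[-length(edges)], upper = edges[-1],
           observed = observed, expected = expected)),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result> chi-square = %.3f on %d df, p = %.4g (%s at alpha = %g)\n",
              x$statistic, x$dof, x$p_value,
              if (x$pass) "pass" else "fail", x$alpha))
  invisible(x)
}

#' Sample one or more years of heat-wave events
#'
#' Draws the annual event count from the Poisson frequency model and i.i.d.
#' Gamma intensities for each event.
#'
#' @param freq a `freq_model`.
#' @param intens an `intensity_model`.
#' @param n_years number of years to sample.
#' @param seed optional RNG seed.
#' @return a list of length `n_years`; element y is the numeric vector of
#'   event intensities in year y (possibly empty).
#' @export
sample_year <- function(freq, intens, n_years = 1L, seed = NULL) {
  stopifnot(inherits(freq, "freq_model"), inherits(intens, "intensity_model"))
  check_that(n_years >= 1, "n_years", "must be >= 1")
  with_seed(seed, {
    counts <- stats::rpois(n_years, freq$lambda)
    total <- sum(counts)
    draws <- if (total > 0) {
      stats::rgamma(total, shape = intens$shape, scale = intens$scale)
    } else numeric(0)
    split(draws, factor(rep(seq_len(n_years), counts),
                        levels = seq_len(n_years)))
  })
}
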