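# Internal helpers.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that no function in the package mutates global randomness as a side
#' effect. With `seed = NULL` the code runs against the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (abs(seed) >= 2^31) stop("'seed' must be a 32-bit integer", call. = FALSE)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a message naming the offending field
#' @noRd
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

#' Fixed public-holiday calendar used by the generator and the model design
#'
#' New Year (Jan 1), Labour Day (May 1-3) and National Day (Oct 1-3):
#' a deterministic function of the date so that simulated data and model
#' design matrices always agree.
#'
#' @param dates a `Date` vector.
#' @return integer vector of 0/1 flags.
#' @export
is_holiday <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  m <- as.integer(format(dates, "%m"))
  d <- as.integer(format(dates, "%d"))
  as.integer((m == 1L & d == 1L) |
    (m == 5L & d <= 3L) |
    (m == 10L & d <= 3L))
}
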