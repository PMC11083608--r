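#' Construct an RR-interval series
#'
#' An `rr_series` is a tibble with one row per interbeat (RR) interval:
#' `time` is the occurrence time (seconds from record start) of the beat that
#' *ends* the interval, `rr` is the interval length in milliseconds, and
#' `label` carries optional per-beat annotations (`"normal"`, `"ectopic"`,
#' `"pause"`). Beat times are the cumulative sum of the intervals added to the
#' start offset `t0`, so `beat_times()` returns `n + 1` times (the beat opening
#' the record plus one per interval).
#'
#' @param intervals Numeric vector of RR intervals in milliseconds, all > 0.
#' @param t0 Time of the first beat (seconds), default 0.
#' @param is_nn Logical flag: has ectopic/artifact filtering been applied
#'   (normal-to-normal intervals)?
#' @param labels Optional character vector of per-interval beat labels.
#'
#' @return A tibble of class `rr_series` with columns `time`, `rr`, `label`.
#' @examples
#' rr <- rr_series(c(800, 810, 800))
#' beat_times(rr)
#' @export
rr_series <- function(intervals, t0 = 0, is_nn = FALSE, labels = NULL) {
  intervals <- as.numeric(intervals)
  assert_that(length(intervals) >= 1L, "an rr_series needs at least one interval")
  assert_that(all(is.finite(intervals)), "RR intervals must be finite")
  assert_that(all(intervals > 0), "RR intervals must be strictly positive (ms)")
  if (is.null(labels)) labels <- rep(NA_character_, length(intervals))
  assert_that(length(labels) == length(intervals),
              "labels must have one entry per interval")
  out <- tibble::tibble(
    time = t0 + cumsum(intervals) / 1000,
    rr = intervals,
    label = labels
  )
  attr(out, "t0") <- t0
  attr(out, "is_nn") <- isTRUE(is_nn)
  class(out) <- c("rr_series", class(out))
  out
}

#' Beat occurrence times of an RR series
#'
#' @param rr An [rr_series()].
#' @return Numeric vector of `n + 1` beat times in seconds, starting at the
#'   record start offset; successive differences equal the intervals in
#'   seconds.
#' @export
beat_times <- function(rr) {
  validate_rr_series(rr)
  c(rr_t0(rr), rr$time)
}

rr_t0 <- function(rr) attr(rr, "t0") %||% (rr$time[1] - rr$rr[1] / 1000)

#' @rdname rr_series
#' @param rr Object to test or validate.
#' @export
is_rr_series <- function(rr) inherits(rr, "rr_series")

#' @rdname rr_series
#' @export
is_nn <- function(rr) isTRUE(attr(rr, "is_nn"))

validate_rr_series <- function(rr) {
  assert_that(is.data.frame(rr) && all(c("time", "rr") %in% names(rr)),
              "expected an rr_series (tibble with columns `time` and `rr`)")
  assert_that(nrow(rr) >= 1L, "rr_series is empty")
  assert_that(all(is.finite(rr$rr)) && all(rr$rr > 0),
              "all RR intervals must be finite and > 0")
  bt <- c(rr_t0(rr), rr$time)
  assert_that(all(diff(bt) > 0), "beat times must be strictly increasing")
  assert_that(max(abs(diff(bt) - rr$rr / 1000)) <= 1e-9,
              "beat times inconsistent with intervals (> 1e-9 s)")
  invisible(rr)
}

#' @export
print.rr_series <- function(x, ...) {
  n <- nrow(x)
  dur <- x$time[n] - rr_t0(x)
  cat(sprintf("<rr_series: %d intervals, %.1f s, mean RR %.1f ms%s>\n",
              n, dur, mean(x$rr), if (is_nn(x)) ", NN-filtered" else ""))
  NextMethod()
}
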