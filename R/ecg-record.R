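#' Construct an ECG record
#'
#' An `ecg_record` is a tibble with one row per sample: `time` in seconds and
#' `voltage` in millivolts, uniformly sampled at `fs` Hz. The sampling rate,
#' start offset and a free-text label travel as attributes.
#'
#' @param voltage Numeric vector of sample values (mV); must be finite.
#' @param fs Sampling rate in Hz, strictly positive.
#' @param t0 Start offset in seconds.
#' @param label Free-text description.
#' @return A tibble of class `ecg_record` with columns `time`, `voltage`.
#' @examples
#' ecg <- ecg_record(sin(2 * pi * 1 * seq(0, 1, by = 1 / 250)), fs = 250)
#' ecg_fs(ecg)
#' @export
ecg_record <- function(voltage, fs, t0 = 0, label = "") {
  voltage <- as.numeric(voltage)
  assert_that(length(voltage) >= 1L, "ECG record must be non-empty")
  assert_that(all(is.finite(voltage)), "ECG samples must be finite (no NaN/Inf)")
  assert_that(is_number(fs) && fs > 0, "sampling rate fs must be a positive number")
  out <- tibble::tibble(
    time = t0 + (seq_along(voltage) - 1) / fs,
    voltage = voltage
  )
  attr(out, "fs") <- fs
  attr(out, "t0") <- t0
  attr(out, "label") <- label
  class(out) <- c("ecg_record", class(out))
  out
}

#' @rdname ecg_record
#' @param ecg An `ecg_record`.
#' @export
ecg_fs <- function(ecg) {
  fs <- attr(ecg, "fs")
  if (is.null(fs)) {
    dt <- diff(ecg$time)
    fs <- 1 / median(dt)
  }
  fs
}

#' @rdname ecg_record
#' @export
is_ecg_record <- function(ecg) inherits(ecg, "ecg_record")

validate_ecg_record <- function(ecg) {
  assert_that(is.data.frame(ecg) && all(c("time", "voltage") %in% names(ecg)),
              "expected an ecg_record (tibble with columns `time` and `voltage`)")
  assert_that(nrow(ecg) >= 1L, "ECG record is empty")
  assert_that(all(is.finite(ecg$voltage)), "ECG samples must be finite")
  invisible(ecg)
}

#' @export
print.ecg_record <- function(x, ...) {
  fs <- ecg_fs(x)
  cat(sprintf("<ecg_record: %d samples @ %g Hz (%.1f s)>\n",
              nrow(x), fs, nrow(x) / fs))
  NextMethod()
}
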