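#' Poincaré plot quantification (SD1, SD2)
#'
#' Builds the lag-`m` Poincaré point cloud (RR(n), RR(n+m)) and quantifies
#' dispersion perpendicular to and along the line of identity:
#' `sd1 = sd((y - x)/sqrt(2))` (short-term variability) and
#' `sd2 = sd((y + x)/sqrt(2))` (long-term variability), using population
#' (divide-by-n) normalization so that `sd1 = rmssd/sqrt(2)` holds exactly
#' whenever the mean successive difference is zero.
#'
#' @param rr An [rr_series()] with at least 3 intervals.
#' @param lag Beat lag between paired intervals (default 1).
#' @return A list of class `hrv_poincare` with `sd1`, `sd2`, `ratio`
#'   (sd1/sd2, `NA` when sd2 = 0) and `points`, a tibble with columns
#'   `rr_n`, `rr_next`.
#' @examples
#' p <- hrv_poincare(rr_series(c(800, 810, 800)))
#' p$sd1
#' @export
hrv_poincare <- function(rr, lag = 1L) {
  validate_rr_series(rr)
  iv <- rr$rr
  n <- length(iv)
  assert_that(n >= 3L, "Poincare analysis needs at least 3 intervals")
  lag <- as.integer(lag)
  assert_that(lag >= 1L && lag < n, "lag must be in [1, n)")
  x <- iv[seq_len(n - lag)]
  y <- iv[seq_len(n - lag) + lag]
  sd1 <- pop_sd((y - x) / sqrt(2))
  sd2 <- pop_sd((y + x) / sqrt(2))
  ratio <- if (sd2 > 0) sd1 / sd2 else NA_real_
  structure(list(
    sd1 = sd1, sd2 = sd2, ratio = ratio, lag = lag,
    points = tibble::tibble(rr_n = x, rr_next = y)
  ), class = "hrv_poincare")
}

#' @export
print.hrv_poincare <- function(x, ...) {
  cat(sprintf("<hrv_poincare: SD1 %.2f ms, SD2 %.2f ms, SD1/SD2 %s (%d points)>\n",
              x$sd1, x$sd2,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
              nrow(x$points)))
  invisible(x)
}
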