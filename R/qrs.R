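#' Pan-Tompkins QRS detection
#'
#' Detects R peaks with the classic Pan-Tompkins pipeline: band-pass
#' (default 5-15 Hz, zero-phase), five-point derivative, pointwise squaring,
#' moving-window integration (150 ms), then adaptive dual-threshold peak
#' classification with a 200 ms refractory period, 360 ms T-wave
#' discrimination (slope test), and search-back with a halved threshold when
#' no beat is found within `searchback_factor` (1.66) times the running RR
#' average. Each accepted fiducial is finally localized as the maximum of
#' the input ECG within +/-100 ms.
#'
#' @param ecg An [ecg_record()], ideally already passed through
#'   [preprocess_ecg()]; sampling rate must be >= 100 Hz and the record at
#'   least 5 s long.
#' @param band Band-pass edges in Hz.
#' @param integration_window Moving integration window in seconds.
#' @param refractory Refractory period in seconds.
#' @param t_wave_window T-wave discrimination window in seconds.
#' @param searchback_factor Missed-beat search-back trigger, in multiples of
#'   the running RR average.
#' @param threshold_coef Signal/noise running-estimate update coefficient.
#' @param localize_window Half-width (s) of the R-peak localization window.
#' @return A list of class `qrs_detection` with `peaks` (a tibble:
#'   `index` 1-based sample, `time` s, `amplitude` mV), `thresholds`
#'   (per-candidate diagnostic trace) and `fs`.
#' @examples
#' rr <- rr_series(rep(1000, 12))
#' out <- synth_ecg(rr, ecg_synth_spec(fs = 250))
#' det <- detect_qrs(out$ecg)
#' nrow(det$peaks)
#' @export
detect_qrs <- function(ecg, band = c(5, 15), integration_window = 0.150,
                       refractory = 0.200, t_wave_window = 0.360,
                       searchback_factor = 1.66, threshold_coef = 0.125,
                       localize_window = 0.100) {
  validate_ecg_record(ecg)
  fs <- ecg_fs(ecg)
  assert_that(fs >= 100, "QRS detection requires fs >= 100 Hz")
  x <- ecg$voltage
  n <- length(x)
  assert_that(n / fs >= 5, "record shorter than 5 s")
  if (var(x) == 0) {
    warn("zero-variance signal: no QRS complexes detected")
    return(empty_detection(fs))
  }

  filt <- bandpass_zerophase(x, fs, band[1], band[2], order = 2)
  # five-point derivative: (1/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4]) * fs
  der <- stats::filter(filt, c(2, 1, 0, -1, -2) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  wi <- max(2L, as.integer(round(integration_window * fs)))
  mwi <- moving_average(sq, wi)

  cand <- local_maxima(mwi)
  if (!length(cand)) return(empty_detection(fs))

  refr <- as.integer(round(refractory * fs))
  twin <- as.integer(round(t_wave_window * fs))
  slope_win <- max(2L, as.integer(round(0.075 * fs)))

  # learning phase: first 2 s of the integrated signal
  init_seg <- mwi[seq_len(min(n, as.integer(2 * fs)))]
  spki <- 0.5 * max(init_seg)
  npki <- 0.5 * mean(init_seg)

  qrs_idx <- integer(0)
  rr_hist <- numeric(0)
  thr_trace <- numeric(length(cand))
  cls_trace <- character(length(cand))
  last_qrs <- -Inf
  last_slope <- Inf
  noise_peaks <- integer(0)  # recent unaccepted candidates (for search-back)

  max_slope_at <- function(i) {
    lo <- max(1L, i - slope_win)
    hi <- min(n, i + slope_win)
    max(abs(diff(filt[lo:hi])))
  }

  accept <- function(i) {
    qrs_idx[[length(qrs_idx) + 1L]] <<- i
    if (is.finite(last_qrs)) {
      rr_hist <<- c(rr_hist, (i - last_qrs) / fs)
      if (length(rr_hist) > 8L) rr_hist <<- tail(rr_hist, 8L)
    }
    last_qrs <<- i
    last_slope <<- max_slope_at(i)
    noise_peaks <<- integer(0)
  }

  for (ci in seq_along(cand)) {
    i <- cand[ci]
    pki <- mwi[i]
    thr1 <- npki + 0.25 * (spki - npki)
    thr_trace[ci] <- thr1
    if (i - last_qrs < refr) {
      cls_trace[ci] <- "refractory"
      next
    }
    is_qrs <- FALSE
    if (pki > thr1) {
      if (is.finite(last_qrs) && (i - last_qrs) < twin &&
          max_slope_at(i) < 0.5 * last_slope) {
        cls_trace[ci] <- "t_wave"
        npki <- threshold_coef * pki + (1 - threshold_coef) * npki
      } else {
        is_qrs <- TRUE
      }
    } else {
      cls_trace[ci] <- "noise"
      npki <- threshold_coef * pki + (1 - threshold_coef) * npki
      noise_peaks <- c(noise_peaks, i)
    }
    if (is_qrs) {
      cls_trace[ci] <- "qrs"
      spki <- threshold_coef * pki + (1 - threshold_coef) * spki
      accept(i)
      next
    }
    # search-back: have we overshot 1.66x the running RR average?
    if (length(rr_hist) >= 2L && is.finite(last_qrs)) {
      rr_avg <- mean(rr_hist)
      if ((i - last_qrs) / fs > searchback_factor * rr_avg &&
          length(noise_peaks)) {
        ok <- noise_peaks[noise_peaks > last_qrs + refr &
                            mwi[noise_peaks] > 0.5 * thr1]
        if (length(ok)) {
          back <- ok[which.max(mwi[ok])]
          spki <- 0.25 * mwi[back] + 0.75 * spki
          accept(back)
        }
      }
    }
  }

  if (!length(qrs_idx)) return(empty_detection(fs))
  qrs_idx <- sort(qrs_idx)

  # localize R peaks on the input ECG within +/- localize_window
  lw <- as.integer(round(localize_window * fs))
  r_idx <- vapply(qrs_idx, function(i) {
    lo <- max(1L, i - lw)
    hi <- min(n, i + lw)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # enforce refractory separation after localization
  if (length(r_idx) > 1L) {
    keep <- c(TRUE, diff(r_idx) >= refr)
    while (!all(keep)) {
      r_idx <- r_idx[keep]
      keep <- c(TRUE, diff(r_idx) >= refr)
    }
  }
  t0 <- attr(ecg, "t0") %||% 0
  structure(list(
    peaks = tibble::tibble(index = r_idx,
                           time = t0 + (r_idx - 1) / fs,
                           amplitude = x[r_idx]),
    thresholds = tibble::tibble(index = cand,
                                time = t0 + (cand - 1) / fs,
                                value = mwi[cand],
                                threshold = thr_trace,
                                class = cls_trace),
    fs = fs
  ), class = "qrs_detection")
}

empty_detection <- function(fs) {
  structure(list(
    peaks = tibble::tibble(index = integer(0), time = numeric(0),
                           amplitude = numeric(0)),
    thresholds = tibble::tibble(index = integer(0), time = numeric(0),
                                value = numeric(0), threshold = numeric(0),
                                class = character(0)),
    fs = fs
  ), class = "qrs_detection")
}

# indices of strict-or-plateau local maxima
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' RR intervals from detected peaks
#'
#' @param det A `qrs_detection` from [detect_qrs()].
#' @return An [rr_series()] (`is_nn = FALSE`) with `intervals[k]` the time
#'   between peaks `k` and `k + 1` in ms.
#' @export
rr_from_peaks <- function(det) {
  assert_that(inherits(det, "qrs_detection"), "expected a qrs_detection")
  assert_that(nrow(det$peaks) >= 2L, "need at least 2 peaks to form intervals")
  iv <- diff(det$peaks$time) * 1000
  rr_series(iv, t0 = det$peaks$time[1], is_nn = FALSE)
}

#' Normal-to-normal (NN) interval filtering
#'
#' Marks as non-normal any interval that differs from the median of the
#' previous `window` accepted intervals by more than a fraction `frac`, or
#' that lies outside the physiological range `[rr_min, rr_max]` ms, and
#' returns the accepted intervals as an NN series. Idempotent: filtering an
#' already filtered series removes nothing further.
#'
#' @param rr An [rr_series()].
#' @param frac Maximum fractional deviation from the running median (0.2).
#' @param window Number of previous accepted intervals for the median (5).
#' @param rr_min,rr_max Physiological interval bounds in ms.
#' @return An [rr_series()] with `is_nn = TRUE`; the attribute `"removed"`
#'   is a tibble logging index, value and reason of every rejected interval.
#' @export
nn_filter <- function(rr, frac = 0.2, window = 5L, rr_min = 300,
                      rr_max = 2000) {
  validate_rr_series(rr)
  iv <- rr$rr
  n <- length(iv)
  accepted <- logical(n)
  reason <- character(n)
  acc_vals <- numeric(0)
  for (k in seq_len(n)) {
    v <- iv[k]
    if (v < rr_min || v > rr_max) {
      reason[k] <- "out_of_range"
      next
    }
    if (length(acc_vals)) {
      ref <- median(tail(acc_vals, window))
      if (abs(v - ref) > frac * ref) {
        reason[k] <- "deviates_from_median"
        next
      }
    }
    accepted[k] <- TRUE
    acc_vals <- c(acc_vals, v)
  }
  assert_that(any(accepted), "NN filter rejected every interval")
  labs <- if ("label" %in% names(rr)) rr$label else rep(NA_character_, n)
  out <- rr_series(iv[accepted], is_nn = TRUE, labels = labs[accepted])
  attr(out, "removed") <- tibble::tibble(
    index = which(!accepted),
    rr = iv[!accepted],
    label = labs[!accepted],
    reason = reason[!accepted]
  )
  out
}
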