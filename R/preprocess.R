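#' ECG preprocessing chain
#'
#' Denoises a raw ECG with four stages applied in order:
#' 1. moving-average smoothing (`w_avg` samples, centered, edge-replicated);
#' 2. DC removal (subtract the record mean);
#' 3. baseline estimation by a running median over `w_med` seconds,
#'    subtracted from the signal;
#' 4. zero-phase (forward-backward) Butterworth low-pass at `f_lp` Hz.
#'
#' Stages 1, 2 and 4 are linear; all four are symmetric/zero-phase so
#' fiducial (R-peak) timing is preserved to within one sample. Any stage can
#' be disabled (`w_avg = 1`, `w_med = NULL`, `f_lp = NULL`).
#'
#' @param ecg An [ecg_record()].
#' @param w_avg Moving-average window in samples (odd recommended; 1 = off).
#' @param w_med Median-filter window in seconds (must be shorter than the
#'   record; NULL = off). Default 0.6 s: longer than any QRS complex,
#'   shorter than a baseline-wander period.
#' @param f_lp Low-pass cutoff in Hz (NULL = off). Applied forward-backward
#'   with an order-`lp_order/2` Butterworth design, giving a zero-phase
#'   filter of effective order `lp_order`.
#' @param lp_order Effective low-pass order (even), default 4.
#' @return An [ecg_record()] of the same length and sampling rate.
#' @export
preprocess_ecg <- function(ecg, w_avg = 5, w_med = 0.6, f_lp = 40,
                           lp_order = 4) {
  validate_ecg_record(ecg)
  fs <- ecg_fs(ecg)
  x <- ecg$voltage
  n <- length(x)
  if (!is.null(w_med)) {
    assert_that(w_med * fs < n,
                "median window w_med must be shorter than the record")
  }
  if (w_avg > 1) x <- moving_average(x, as.integer(w_avg))
  x <- x - mean(x)
  if (!is.null(w_med) && w_med > 0) {
    k <- as.integer(round(w_med * fs))
    if (k %% 2L == 0L) k <- k + 1L
    if (k >= 3L && k < n) {
      baseline <- as.numeric(runmed(x, k, endrule = "median"))
      x <- x - baseline
    }
  }
  if (!is.null(f_lp) && f_lp > 0 && f_lp < fs / 2) {
    x <- lowpass_zerophase(x, fs, f_lp, lp_order)
  }
  out <- ecg_record(x, fs = fs, t0 = attr(ecg, "t0") %||% 0,
                    label = attr(ecg, "label") %||% "")
  out
}

# Centered moving average with edge replication (keeps length and phase).
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  half <- w %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], w - half - 1L))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 1))[w:(length(xp))][seq_along(x)]
}

# Zero-phase Butterworth low-pass: forward-backward pass of order `order/2`.
lowpass_zerophase <- function(x, fs, fc, order = 4) {
  half_order <- max(1L, as.integer(order / 2))
  bf <- signal::butter(half_order, fc / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Zero-phase Butterworth band-pass (used by the QRS detector).
bandpass_zerophase <- function(x, fs, flo, fhi, order = 2) {
  bf <- signal::butter(order, c(flo, fhi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}
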