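#' ECG synthesis specification
#'
#' Parameters for building a ground-truth ECG from an RR series: a
#' parameterized P-QRS-T beat template (sums of Gaussians, amplitudes in mV,
#' centers/widths in ms relative to the R peak) plus additive baseline
#' wander, powerline interference and white noise.
#'
#' @param fs Sampling rate in Hz (>= 100).
#' @param waves Tibble/data frame with columns `wave`, `amp` (mV),
#'   `center` (ms from R), `width` (ms, Gaussian sd). The default describes a
#'   standard positive-R lead-II-like beat.
#' @param baseline_wander_amp,baseline_wander_freq Baseline wander sinusoid
#'   (mV, Hz).
#' @param powerline_amp,powerline_freq Powerline interference (mV, Hz).
#' @param white_noise_sd Additive white Gaussian noise sd (mV).
#' @return A list of class `ecg_synth_spec`.
#' @export
ecg_synth_spec <- function(fs = 250,
                           waves = default_beat_waves(),
                           baseline_wander_amp = 0,
                           baseline_wander_freq = 0.3,
                           powerline_amp = 0,
                           powerline_freq = 50,
                           white_noise_sd = 0) {
  assert_that(is_number(fs) && fs >= 100, "fs must be >= 100 Hz")
  waves <- tibble::as_tibble(waves)
  assert_that(all(c("wave", "amp", "center", "width") %in% names(waves)),
              "waves needs columns wave, amp, center, width")
  structure(list(fs = fs, waves = waves,
                 baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_freq = baseline_wander_freq,
                 powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq,
                 white_noise_sd = white_noise_sd),
            class = "ecg_synth_spec")
}

#' @rdname ecg_synth_spec
#' @export
default_beat_waves <- function() {
  tibble::tibble(
    wave   = c("P",  "Q",   "R",  "S",   "T"),
    amp    = c(0.12, -0.15, 1.0, -0.20, 0.30),
    center = c(-160, -22,   0,    22,   230),
    width  = c(25,   8,     12,   9,    45)
  )
}

# QRS span of the template (ms): from Q onset to S offset at 3 sd.
template_qrs_width <- function(spec) {
  qrs <- spec$waves[spec$waves$wave %in% c("Q", "R", "S"), ]
  max(qrs$center + 3 * qrs$width) - min(qrs$center - 3 * qrs$width)
}

#' Synthesize a ground-truth ECG from an RR series
#'
#' Places one beat template per beat of `rr` at the cumulative beat times
#' (plus a 1 s lead-in so filters can settle) and adds baseline wander,
#' powerline interference and white noise per the spec. The returned truth
#' peaks are the exact sample indices of the template R-wave centers.
#'
#' @param rr An [rr_series()]; one beat is placed per beat time (`n` beats
#'   for `n` intervals, at times `beat_times(rr)[1:n]`, so the first `n - 1`
#'   intervals separate consecutive beats).
#' @param spec An [ecg_synth_spec()].
#' @param seed Seed for the noise components.
#' @return A list with `ecg` (an [ecg_record()]) and `truth_peaks`
#'   (integer sample indices of the R peaks, 1-based).
#' @examples
#' rr <- rr_series(rep(1000, 10))
#' out <- synth_ecg(rr, ecg_synth_spec(fs = 250))
#' diff(out$truth_peaks)
#' @export
synth_ecg <- function(rr, spec = ecg_synth_spec(), seed = 1L) {
  validate_rr_series(rr)
  assert_that(inherits(spec, "ecg_synth_spec"), "spec must be an ecg_synth_spec")
  assert_that(template_qrs_width(spec) < min(rr$rr),
              "QRS template wider than the shortest RR interval")
  fs <- spec$fs
  lead_in <- 1.0
  bt <- head(beat_times(rr), nrow(rr)) - rr_t0(rr) + lead_in
  n_samp <- ceiling((max(bt) + 1.0) * fs) + 1L
  truth <- as.integer(round(bt * fs)) + 1L
  x <- numeric(n_samp)
  # template support: +/- 450 ms around R covers P and T at 3 sd
  half <- ceiling(0.45 * fs)
  offs_ms <- (-half:half) / fs * 1000
  template <- rowSums(vapply(seq_len(nrow(spec$waves)), function(i) {
    w <- spec$waves[i, ]
    w$amp * exp(-((offs_ms - w$center)^2) / (2 * w$width^2))
  }, numeric(length(offs_ms))))
  for (p in truth) {
    lo <- max(1L, p - half)
    hi <- min(n_samp, p + half)
    x[lo:hi] <- x[lo:hi] + template[(lo - p + half + 1L):(hi - p + half + 1L)]
  }
  t <- (seq_len(n_samp) - 1) / fs
  withr::with_seed(seed, {
    if (spec$baseline_wander_amp > 0) {
      ph <- runif(1, 0, 2 * pi)
      x <- x + spec$baseline_wander_amp *
        sin(2 * pi * spec$baseline_wander_freq * t + ph)
    }
    if (spec$powerline_amp > 0) {
      x <- x + spec$powerline_amp * sin(2 * pi * spec$powerline_freq * t)
    }
    if (spec$white_noise_sd > 0) {
      x <- x + rnorm(n_samp, 0, spec$white_noise_sd)
    }
  })
  list(ecg = ecg_record(x, fs = fs, label = "synthetic"), truth_peaks = truth)
}
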