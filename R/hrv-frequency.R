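#' Resample a tachogram onto a uniform grid
#'
#' Cubic-spline interpolation of the tachogram points (beat time, interval
#' length) evaluated on a uniform grid spanning the first to the last beat
#' time — the standard preparation step before Welch spectral analysis of
#' RR series. No extrapolation beyond the observed beats.
#'
#' @param rr An [rr_series()] with at least 4 beats.
#' @param fs_resample Resampling rate in Hz (default 4; must exceed twice
#'   the upper HF band edge, 0.4 Hz).
#' @return A tibble with columns `time` (s) and `rr` (ms) on the uniform
#'   grid; the attribute `"fs"` carries the resampling rate.
#' @export
resample_tachogram <- function(rr, fs_resample = 4) {
  validate_rr_series(rr)
  assert_that(nrow(rr) >= 4L, "resampling needs at least 4 beats")
  assert_that(fs_resample > 0.8, "fs_resample must exceed 2 x 0.4 Hz")
  tt <- rr$time
  dur <- tt[length(tt)] - tt[1]
  assert_that(dur >= 10, "tachogram shorter than 10 s cannot be resampled")
  if (dur < 60) warn("tachogram shorter than 60 s: spectral estimates unstable")
  f <- splinefun(tt, rr$rr, method = "fmm")
  grid <- seq(tt[1], tt[length(tt)], by = 1 / fs_resample)
  out <- tibble::tibble(time = grid, rr = f(grid))
  attr(out, "fs") <- fs_resample
  out
}

#' Welch averaged-periodogram PSD
#'
#' Splits the (mean-removed) series into `K` overlapping segments of
#' `seg_len` samples, applies a Hamming window `w(n)` to each, normalizes
#' each modified periodogram by the window power \eqn{U = (1/M)\sum w(n)^2},
#' and averages over segments. The one-sided density is finally scaled so
#' that its trapezoidal integral over the full frequency axis equals the
#' (population) variance of the input — band powers then come out in
#' ms\eqn{^2}.
#'
#' @param x Numeric vector (or tibble from [resample_tachogram()], column
#'   `rr`), uniformly sampled.
#' @param fs Sampling rate in Hz (taken from the tibble attribute if absent).
#' @param seg_len Segment length M in samples (default 256 = 64 s at 4 Hz).
#' @param overlap Overlap fraction in [0, 1), default 0.5.
#' @return A tibble with columns `freq` (Hz) and `psd` (ms^2/Hz); attributes
#'   `"settings"` (list) and `"variance"`.
#' @export
welch_psd <- function(x, fs = NULL, seg_len = 256, overlap = 0.5) {
  if (is.data.frame(x)) {
    fs <- fs %||% attr(x, "fs")
    x <- x$rr
  }
  assert_that(!is.null(fs) && is_number(fs) && fs > 0, "fs must be supplied")
  x <- as.numeric(x)
  n <- length(x)
  assert_that(seg_len >= 8, "seg_len must be at least 8 samples")
  assert_that(n >= seg_len, "series shorter than one segment")
  assert_that(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)")
  x <- x - mean(x)
  v <- mean(x^2)  # population variance of the detrended series

  M <- as.integer(seg_len)
  step <- max(1L, as.integer(round(M * (1 - overlap))))
  starts <- seq(1L, n - M + 1L, by = step)
  K <- length(starts)
  w <- hamming_window(M)
  U <- mean(w^2)
  nf <- M %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + M - 1L)] * w
    X <- fft(seg)
    p <- (Mod(X)^2)[seq_len(nf)] / (M * U)  # modified periodogram, per Eq. form
    acc <- acc + p
  }
  p2 <- acc / K                      # averaged over the K windows
  # one-sided density: double interior bins, divide by fs for per-Hz units
  p1 <- p2 * 2 / fs
  p1[c(1L, nf)] <- p1[c(1L, nf)] / 2
  freqs <- (seq_len(nf) - 1L) * fs / M
  if (v > 0) {
    tot <- trapz(freqs, p1)
    if (tot > 0) p1 <- p1 * (v / tot)
  } else {
    p1[] <- 0
  }
  out <- tibble::tibble(freq = freqs, psd = p1)
  attr(out, "settings") <- list(seg_len = M, overlap = overlap, fs = fs,
                                n_segments = K, window = "hamming")
  attr(out, "variance") <- v
  out
}

hamming_window <- function(M) {
  0.54 - 0.46 * cos(2 * pi * (0:(M - 1)) / (M - 1))
}

#' Band powers and normalized units from a PSD
#'
#' Integrates the PSD (trapezoidal rule, interpolated at band edges) over
#' the conventional HRV bands — VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz, HF
#' 0.15-0.4 Hz — and derives normalized units `lf_nu = LF/(LF+HF)`,
#' `hf_nu = HF/(LF+HF)` and the `lf_hf` ratio.
#'
#' @param psd A tibble with `freq` and `psd` columns (from [welch_psd()]).
#' @param bands Named list of `c(lo, hi)` band edges in Hz.
#' @return A one-row tibble of class `hrv_spectrum_bands`: `vlf_power`,
#'   `lf_power`, `hf_power` (ms^2), `total_power`, `lf_nu`, `hf_nu`, `lf_hf`.
#' @export
band_powers <- function(psd,
                        bands = list(vlf = c(0.003, 0.04),
                                     lf = c(0.04, 0.15),
                                     hf = c(0.15, 0.4))) {
  assert_that(is.data.frame(psd) && all(c("freq", "psd") %in% names(psd)),
              "psd must have columns `freq` and `psd`")
  f <- psd$freq
  p <- psd$psd
  assert_that(all(diff(f) > 0), "frequency grid must be increasing")
  assert_that(f[1] <= 0.003 && f[length(f)] >= 0.4,
              "frequency grid must cover 0.003-0.4 Hz")
  pw <- vapply(bands, function(b) band_integral(f, p, b[1], b[2]), numeric(1))
  lf <- pw[["lf"]]; hf <- pw[["hf"]]
  lf_hf <- if (hf > 0) lf / hf else {
    warn("HF power is zero: LF/HF undefined")
    NA_real_
  }
  denom <- lf + hf
  out <- tibble::tibble(
    vlf_power = pw[["vlf"]], lf_power = lf, hf_power = hf,
    total_power = sum(pw),
    lf_nu = if (denom > 0) lf / denom else NA_real_,
    hf_nu = if (denom > 0) hf / denom else NA_real_,
    lf_hf = lf_hf
  )
  class(out) <- c("hrv_spectrum_bands", class(out))
  out
}

# trapezoidal integral of p over [lo, hi), with interpolated edge points
band_integral <- function(f, p, lo, hi) {
  lo <- max(lo, f[1]); hi <- min(hi, f[length(f)])
  if (hi <= lo) return(0)
  inside <- f > lo & f < hi
  fx <- c(lo, f[inside], hi)
  px <- c(interp_at(f, p, lo), p[inside], interp_at(f, p, hi))
  trapz(fx, px)
}

#' Full spectral HRV analysis of an RR series
#'
#' Convenience wrapper: [resample_tachogram()] at `fs_resample`, then
#' [welch_psd()], then [band_powers()].
#'
#' @inheritParams resample_tachogram
#' @inheritParams welch_psd
#' @inheritParams band_powers
#' @return A list of class `hrv_spectrum` with `psd` (tibble `freq`, `psd`),
#'   `bands` (one-row tibble), and `settings`.
#' @examples
#' rr <- synth_rr(cohort_spec("healthy"), duration = 300, seed = 1)
#' sp <- hrv_frequency(rr)
#' sp$bands$lf_nu + sp$bands$hf_nu
#' @export
hrv_frequency <- function(rr, fs_resample = 4, seg_len = 256, overlap = 0.5,
                          bands = list(vlf = c(0.003, 0.04),
                                       lf = c(0.04, 0.15),
                                       hf = c(0.15, 0.4))) {
  tach <- resample_tachogram(rr, fs_resample)
  if (nrow(tach) < seg_len) seg_len <- 2^floor(log2(nrow(tach)))
  psd <- welch_psd(tach, seg_len = seg_len, overlap = overlap)
  bp <- band_powers(psd, bands = bands)
  structure(list(psd = psd, bands = bp,
                 settings = attr(psd, "settings")),
            class = "hrv_spectrum")
}

#' @export
print.hrv_spectrum <- function(x, ...) {
  b <- x$bands
  cat(sprintf(
    "<hrv_spectrum: VLF %.1f  LF %.1f  HF %.1f ms^2 | LF nu %.2f HF nu %.2f LF/HF %.2f>\n",
    b$vlf_power, b$lf_power, b$hf_power, b$lf_nu, b$hf_nu, b$lf_hf))
  invisible(x)
}
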