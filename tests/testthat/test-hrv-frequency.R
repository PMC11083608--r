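test_that("tachogram resampling is exact on constants and accurate on sines", {
  const <- resample_tachogram(rr_series(rep(800, 200)))
  expect_lt(max(abs(const$rr - 800)), 1e-9)
  expect_equal(diff(const$time)[1], 0.25, tolerance = 1e-12)

  # slow sine riding on the tachogram; each interval takes the sine value
  # at its ending beat time (fixed-point per beat, matching the abscissa
  # convention of the resampler)
  n <- 400
  iv <- numeric(n); t <- 0
  for (k in 1:n) {
    v <- 900
    for (it in 1:6) v <- 900 + 80 * sin(2 * pi * 0.05 * (t + v / 1000))
    iv[k] <- v
    t <- t + v / 1000
  }
  rr <- rr_series(iv)
  rs <- resample_tachogram(rr)
  truth <- 900 + 80 * sin(2 * pi * 0.05 * rs$time)
  expect_lt(sqrt(mean((rs$rr - truth)^2)) / 80, 0.01)

  expect_error(resample_tachogram(rr_series(rep(800, 5))),
               class = "hrv_validation_error")
})

test_that("Welch PSD integrates to the series variance", {
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(1024, sd = 3)
    p <- welch_psd(x, fs = 4)
    v <- mean((x - mean(x))^2)
    expect_lt(abs(hrvkit:::trapz(p$freq, p$psd) - v) / v, 0.05)
  }
  expect_true(all(welch_psd(rnorm(512), fs = 4)$psd >= 0))
})

test_that("constant input has an identically zero spectrum", {
  p <- welch_psd(rep(5, 512), fs = 4)
  expect_true(all(p$psd == 0))
})

test_that("no overlap and full-length segment reduce to one periodogram", {
  set.seed(2)
  x <- rnorm(256)
  p <- welch_psd(x, fs = 4, seg_len = 256, overlap = 0)
  expect_equal(attr(p, "settings")$n_segments, 1)
  # independent single modified periodogram with the same scaling
  xc <- x - mean(x)
  M <- 256
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(M - 1)) / (M - 1))
  raw <- Mod(fft(xc * w))^2 / (M * mean(w^2))
  one <- raw[1:129] * 2 / 4
  one[c(1, 129)] <- one[c(1, 129)] / 2
  fr <- (0:128) * 4 / 256
  one <- one * mean(xc^2) / hrvkit:::trapz(fr, one)
  expect_equal(p$psd, one, tolerance = 1e-9)
})

test_that("sinusoidal modulations land in their spectral bands", {
  mk <- function(f_mod) {
    amp_args <- if (f_mod > 0.15) {
      list(rsa_amp = 30, rsa_freq = f_mod, lf_amp = 0, vlf_amp = 0)
    } else {
      list(rsa_amp = 0, lf_amp = 30, lf_freq = f_mod, vlf_amp = 0)
    }
    spec <- do.call(cohort_spec,
                    c(list("healthy", noise_sd = 0), amp_args))
    hrv_frequency(synth_rr(spec, duration = 300, seed = 3))$bands
  }
  lf_case <- mk(0.10)
  tot <- lf_case$vlf_power + lf_case$lf_power + lf_case$hf_power
  expect_gt(lf_case$lf_power / tot, 0.9)

  hf_case <- mk(0.30)
  tot <- hf_case$vlf_power + hf_case$lf_power + hf_case$hf_power
  expect_gt(hf_case$hf_power / tot, 0.9)

  expect_equal(lf_case$lf_nu + lf_case$hf_nu, 1, tolerance = 1e-9)
})

test_that("band power scales quadratically with modulation amplitude", {
  pw <- vapply(c(15, 30), function(a) {
    spec <- cohort_spec("healthy", rsa_amp = 0, lf_amp = a, vlf_amp = 0,
                        noise_sd = 0)
    hrv_frequency(synth_rr(spec, duration = 300, seed = 6))$bands$lf_power
  }, numeric(1))
  expect_lt(abs(pw[2] / pw[1] - 4), 0.2)
})

test_that("band powers never exceed the tachogram variance", {
  for (s in 1:5) {
    rr <- synth_rr(cohort_spec("healthy"), duration = 300, seed = 40 + s)
    tach <- resample_tachogram(rr)
    b <- hrv_frequency(rr)$bands
    v <- mean((tach$rr - mean(tach$rr))^2)
    expect_lte(b$total_power, v * (1 + 1e-9))
  }
})
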