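test_that("generator is deterministic and hits the target mean", {
  spec <- cohort_spec("healthy")
  a <- synth_rr(spec, duration = 120, seed = 42)
  b <- synth_rr(spec, duration = 120, seed = 42)
  expect_identical(a$rr, b$rr)
  expect_identical(a$label, b$label)

  # noise-only spec, long record: sample mean near the programmed mean RR
  long <- synth_rr(cohort_spec("healthy", rsa_amp = 0, lf_amp = 0,
                               vlf_amp = 0),
                   duration = 2400, seed = 7)
  expect_lt(abs(mean(long$rr) - 892), 10)
})

test_that("ectopic beats appear at the programmed rate with correct labels", {
  spec <- cohort_spec("arrhythmia", ectopy_rate = 0.1,
                      ectopy_prematurity = 0.6, compensatory_pause = 1.4)
  rr <- synth_rr(spec, duration = 780, seed = 5)  # ~1000 beats
  expect_gt(nrow(rr), 900)
  frac <- mean(rr$label == "ectopic")
  expect_lt(abs(frac - 0.1), 0.03)
  # every ectopic is followed by a pause
  ect <- which(rr$label == "ectopic")
  ect <- ect[ect < nrow(rr)]
  expect_true(all(rr$label[ect + 1] == "pause"))
  # ectopics are genuinely premature, pauses genuinely long
  expect_lt(mean(rr$rr[rr$label == "ectopic"]),
            0.75 * mean(rr$rr[rr$label == "normal"]))
  expect_gt(mean(rr$rr[rr$label == "pause"]),
            1.2 * mean(rr$rr[rr$label == "normal"]))
})

test_that("a single HF modulation concentrates spectral power in HF", {
  spec <- cohort_spec("healthy", rsa_amp = 30, rsa_freq = 0.25,
                      lf_amp = 0, vlf_amp = 0, noise_sd = 0)
  rr <- synth_rr(spec, duration = 300, seed = 9)
  b <- hrv_frequency(rr)$bands
  expect_gt(b$hf_power / (b$vlf_power + b$lf_power + b$hf_power), 0.9)
})

test_that("RMSSD of generated series matches the analytic generator value", {
  spec <- cohort_spec("healthy")  # modulations + 15 ms noise
  target <- expected_rmssd(spec)
  got <- vapply(1:50, function(s) {
    rr <- synth_rr(spec, duration = 1800, seed = s)  # ~2000 beats
    sqrt(mean(diff(rr$rr)^2))
  }, numeric(1))
  expect_lt(abs(mean(got) - target) / target, 0.10)
})

test_that("syncope-like series show torpedo-shaped Poincare clouds", {
  rr <- synth_rr(cohort_spec("syncope"), duration = 600, seed = 21)
  p <- hrv_poincare(rr)
  expect_lt(p$sd1, p$sd2 / 3)
})

test_that("cohort_spec rejects invalid parameter combinations", {
  expect_error(cohort_spec("healthy", ectopy_rate = 1.2),
               class = "hrv_validation_error")
  expect_error(cohort_spec("healthy", rsa_freq = 0.5),
               class = "hrv_validation_error")
  expect_error(synth_rr(cohort_spec("healthy"), duration = 30),
               class = "hrv_validation_error")
})

test_that("synthetic ECG places template beats exactly at the truth peaks", {
  rr <- rr_series(rep(1000, 60))
  out <- synth_ecg(rr, ecg_synth_spec(fs = 250))
  expect_length(out$truth_peaks, 60)
  expect_true(all(diff(out$truth_peaks) == 250))
  # R amplitude at each truth sample is the template maximum
  expect_true(all(abs(out$ecg$voltage[out$truth_peaks] -
                        max(out$ecg$voltage)) < 1e-9))
  # noise-free synthesis is deterministic and purely template-driven
  out2 <- synth_ecg(rr, ecg_synth_spec(fs = 250))
  expect_identical(out$ecg$voltage, out2$ecg$voltage)
})

test_that("powerline interference shows up at its line frequency", {
  rr <- rr_series(rep(900, 40))
  clean <- synth_ecg(rr, ecg_synth_spec(fs = 250))
  hum <- synth_ecg(rr, ecg_synth_spec(fs = 250, powerline_amp = 0.2,
                                      powerline_freq = 50))
  a_clean <- amp_at(clean$ecg$voltage, 250, 50)
  a_hum <- amp_at(hum$ecg$voltage, 250, 50)
  expect_gt(a_hum, 10 * max(a_clean, 1e-6))
  expect_gt(a_hum, 0.15)
})

test_that("a QRS template wider than the shortest RR is rejected", {
  rr <- rr_series(rep(90, 80))
  expect_error(synth_ecg(rr, ecg_synth_spec(fs = 250)),
               class = "hrv_validation_error")
})
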