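test_that("hand-checked series give the textbook index values", {
  const <- hrv_time(rr_series(rep(800, 20), is_nn = TRUE))
  expect_equal(const$sdnn, 0)
  expect_equal(const$rmssd, 0)
  expect_equal(const$pnn50, 0)

  alt <- hrv_time(rr_series(c(800, 810, 800, 810), is_nn = TRUE))
  expect_equal(alt$rmssd, 10)
  expect_equal(alt$pnn50, 0)
  expect_equal(alt$mean_rr, 805)

  expect_error(hrv_time(rr_series(810, is_nn = TRUE)),
               class = "hrv_validation_error")
})

test_that("a 40-minute record yields eight 5-minute segments", {
  rr <- rr_series(rep(1000, 2400), is_nn = TRUE)
  td <- hrv_time(rr)
  expect_equal(td$segment_count, 8)
  expect_equal(td$sdann, 0)
})

test_that("indices match direct-formula oracles on random series", {
  for (s in 1:25) {
    iv <- random_rr(600 + (s %% 5) * 200, seed = s)
    td <- hrv_time(rr_series(iv, is_nn = TRUE))
    oc <- oracle_time_domain(iv)
    for (nm in c("mean_rr", "sdnn", "rmssd", "pnn50")) {
      expect_lt(abs(td[[nm]] - oc[[nm]]) / max(oc[[nm]], 1), 1e-9,
                label = paste(nm, "seed", s))
    }
    if (!is.na(oc$sdann)) {
      expect_lt(abs(td$sdann - oc$sdann) / oc$sdann, 1e-9)
      expect_lt(abs(td$sdnn_index - oc$sdnn_index) / oc$sdnn_index, 1e-9)
    } else {
      expect_true(is.na(td$sdann))
    }
  }
})

test_that("scaling intervals scales the ms-denominated indices", {
  iv <- random_rr(900, seed = 77)
  a <- hrv_time(rr_series(iv, is_nn = TRUE))
  # scaling time by 2 means thresholds and segment windows scale with it
  b <- hrv_time(rr_series(2 * iv, is_nn = TRUE), pnn_threshold = 100,
                segment_seconds = 600)
  for (nm in c("mean_rr", "sdnn", "rmssd", "sdann", "sdnn_index")) {
    if (!is.na(a[[nm]])) {
      expect_equal(b[[nm]], 2 * a[[nm]], tolerance = 1e-12, label = nm)
    }
  }
  expect_equal(b$pnn50, a$pnn50)  # threshold scaled with the data
})

test_that("histograms conserve counts and track the mode", {
  iv <- random_rr(500, seed = 4)
  h <- rr_histogram(rr_of(iv))
  expect_equal(sum(h$counts), length(iv))
  expect_equal(diff(h$breaks), rep(h$bin_width, length(h$counts)),
               tolerance = 1e-9)

  single <- rr_histogram(rr_of(rep(803, 40)))
  expect_equal(sum(single$counts > 0), 1)

  tachy <- rr_histogram(rr_of(pmax(300, rnorm(300, 500, 20))))
  brady <- rr_histogram(rr_of(rnorm(300, 1100, 20)))
  expect_lt(tachy$breaks[tachy$mode_bin], brady$breaks[brady$mode_bin])

  expect_error(rr_histogram(rr_of(iv), bin_width = 0),
               class = "hrv_validation_error")
})

test_that("geometric indices: degenerate, uniform and triangular shapes", {
  single <- rr_histogram(rr_of(rep(800, 128)))
  g1 <- geometric_indices(single)
  expect_equal(g1$hrv_ti, 1)
  expect_equal(g1$tinn, 0)

  # four adjacent equally tall bins: HRVTi = 128 / 32 = 4
  bw <- 7.8125
  iv <- rep(bw * c(100.5, 101.5, 102.5, 103.5), each = 32)
  g2 <- geometric_indices(rr_histogram(rr_of(iv), bin_width = bw))
  expect_equal(g2$hrv_ti, 4)

  # symmetric 9-bin triangle: TINN within one bin width of 9 bins
  counts <- c(1, 2, 3, 4, 5, 4, 3, 2, 1)
  iv_tri <- rep(bw * (100.5 + 0:8), times = counts * 4)
  h <- rr_histogram(rr_of(iv_tri), bin_width = bw)
  g3 <- geometric_indices(h)
  expect_lte(abs(g3$tinn - 9 * bw), bw)
  expect_equal(g3$tinn, oracle_tinn(h$counts, h$breaks))
})

test_that("geometric indices agree with the brute-force oracle on random data", {
  for (s in 1:10) {
    iv <- random_rr(400, seed = 100 + s)
    h <- rr_histogram(rr_of(iv))
    g <- geometric_indices(h)
    expect_equal(g$hrv_ti, length(iv) / max(h$counts))
    expect_equal(g$tinn, oracle_tinn(h$counts, h$breaks), label = paste("seed", s))
  }
})
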