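test_that("AMI at lag zero equals the marginal entropy estimate", {
  set.seed(4)
  x <- rnorm(2000)
  a <- ami(x, tau_max = 5)
  breaks <- seq(min(x), max(x), length.out = 17)
  cuts <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1), 16)
  p <- table(cuts) / length(x)
  expect_equal(a$curve$ami[1], -sum(p * log(p)), tolerance = 1e-9)
})

test_that("iid noise carries almost no mutual information at lag one", {
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    suppressWarnings(ami(runif(10000), tau_max = 3))$curve$ami[2]
  }, numeric(1))
  expect_lte(mean(vals), 0.05)
})

test_that("the AMI first minimum of a sampled sine sits at quarter period", {
  t <- 0:16383
  base <- sin(2 * pi * t / 64)
  for (s in 1:5) {
    set.seed(s)
    a <- ami(base + rnorm(length(t), 0, 0.1), tau_max = 32)
    expect_true(abs(a$tau_opt - 16) <= 1, label = paste("seed", s))
  }
})

test_that("AMI of the reversed series matches the original", {
  set.seed(6)
  x <- as.numeric(arima.sim(list(ar = 0.8), 10000))
  a <- suppressWarnings(ami(x, tau_max = 10))$curve$ami
  b <- suppressWarnings(ami(rev(x), tau_max = 10))$curve$ami
  expect_lt(max(abs(a - b) / pmax(a, 0.01)), 0.05)
})

test_that("constant series are rejected by both diagnostics", {
  expect_error(ami(rep(1, 100), tau_max = 5), class = "hrv_validation_error")
  expect_error(fnn(rep(1, 200), tau = 2), class = "hrv_validation_error")
})

test_that("a noise-free sine needs exactly two embedding dimensions", {
  x <- sin(2 * pi * (0:4095) / 64)
  f <- fnn(x, tau = 16, m_max = 5)
  expect_equal(f$m_opt, 2)
  expect_lt(f$curve$fnn_pct[2], 1)
  expect_true(all(f$curve$fnn_pct >= 0 & f$curve$fnn_pct <= 100))
  # non-increasing up to m_opt
  expect_true(all(diff(f$curve$fnn_pct[1:f$m_opt]) <= 0))
})

test_that("iid noise shows more false neighbors than a planar limit cycle", {
  x <- sin(2 * pi * (0:2047) / 64)
  f_sine <- fnn(x, tau = 16, m_max = 3)
  set.seed(12)
  f_noise <- suppressWarnings(fnn(runif(2048), tau = 1, m_max = 3))
  expect_gt(f_noise$curve$fnn_pct[1], f_sine$curve$fnn_pct[2])
})

test_that("attractor export obeys its count and shape contracts", {
  const <- attractor3d(rep(2, 100), tau = 10)
  expect_equal(nrow(const), 80)
  expect_true(all(const$x == 2 & const$y == 2 & const$z == 2))

  x <- sin(2 * pi * (0:999) / 64)
  at <- attractor3d(x, tau = 16)
  ext <- vapply(at, function(col) diff(range(col)), numeric(1))
  expect_lt(max(ext) / min(ext) - 1, 0.05)

  expect_error(attractor3d(x, tau = 0), class = "hrv_validation_error")
  expect_error(attractor3d(x[1:30], tau = 16), class = "hrv_validation_error")
})

test_that("embedding diagnostics feed the RQA pipeline with finite values", {
  rr <- synth_rr(cohort_spec("healthy"), duration = 300, seed = 8)
  emb <- suppressWarnings(hrv_embedding(rr))
  expect_true(is.finite(emb$tau_opt) && emb$tau_opt >= 1)
  expect_true(is.finite(emb$m_opt) && emb$m_opt >= 1)
  expect_equal(nrow(emb$attractor), nrow(rr) - 2 * emb$tau_opt)
  rq <- suppressWarnings(hrv_rqa(rr))
  expect_true(is.finite(rq$rec))
})
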