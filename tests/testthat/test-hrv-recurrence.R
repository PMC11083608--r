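test_that("recurrence matrices for simple constructions", {
  R <- recurrence_matrix(rep(3, 8), m = 1, tau = 1, epsilon = 0.5)
  expect_true(all(R))

  x <- c(0, 1, 0, 1, 0, 1)
  R2 <- recurrence_matrix(x, m = 1, tau = 1, epsilon = 0.5)
  same_parity <- outer(1:6, 1:6, function(i, j) (i - j) %% 2 == 0)
  expect_identical(unname(R2), same_parity)

  set.seed(1)
  R3 <- recurrence_matrix(rnorm(40), m = 2, tau = 2, epsilon = 1)
  expect_identical(R3, t(R3))
  expect_true(all(diag(R3)))
})

test_that("saturated and single-line matrices quantify as expected", {
  allr <- rqa(matrix(TRUE, 10, 10))
  expect_equal(allr$rec, 100)
  # with the identity line removed, the two corner points sit on length-1
  # diagonals; all other 88 recurrent points lie on lines >= 2
  expect_equal(allr$det, 100 * 88 / 90)
  expect_equal(allr$lam, 100 * 88 / 90)
  expect_gte(min(allr$det, allr$lam), 95)

  # one diagonal line of length 5 (plus its symmetric copy)
  R <- diag(10) == 1
  for (k in 1:5) { R[k, k + 5] <- TRUE; R[k + 5, k] <- TRUE }
  out <- rqa(R)
  expect_equal(out$diag_hist$length, 5)
  expect_equal(out$diag_hist$count, 2)
  expect_equal(out$entr, 0)
  expect_equal(out$rec, 100 * 10 / 90)
})

test_that("no recurrent points off the identity line yields nulls", {
  out <- rqa(diag(6) == 1)
  expect_equal(out$rec, 0)
  expect_true(is.na(out$det))
  expect_true(is.na(out$lam))
  expect_true(is.na(out$entr))
})

test_that("quantification matches the naive double-loop oracle exactly", {
  for (s in 1:8) {
    set.seed(500 + s)
    n <- sample(60:160, 1)
    x <- rnorm(n)
    m <- sample(1:3, 1); tau <- sample(1:2, 1)
    eps <- 0.4 * sd(x)
    R <- recurrence_matrix(x, m = m, tau = tau, epsilon = eps)
    got <- rqa(R)
    ora <- naive_rqa(x, m, tau, eps)
    expect_equal(got$rec, ora$rec, tolerance = 1e-12)
    expect_equal(got$det, ora$det, tolerance = 1e-12)
    expect_equal(got$lam, ora$lam, tolerance = 1e-12)
    expect_equal(got$entr, ora$entr, tolerance = 1e-12)
    expect_identical(sort(rep(got$diag_hist$length, got$diag_hist$count)),
                     as.integer(ora$diag_lengths))
    expect_identical(sort(rep(got$vert_hist$length, got$vert_hist$count)),
                     as.integer(ora$vert_lengths))
  }
})

test_that("recurrence rate grows monotonically with the threshold", {
  set.seed(3)
  x <- rnorm(120)
  recs <- vapply(seq(0.2, 2, by = 0.3), function(e)
    rqa(recurrence_matrix(x, epsilon = e * sd(x)))$rec, numeric(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("periodic RR series are highly deterministic, iid ones less so", {
  t <- seq(0, 0.8 * 199, by = 0.8)
  per <- rr_series(800 + 50 * sin(2 * pi * 0.25 * t))
  rq_per <- hrv_rqa(per, m = 2, tau = 1)
  expect_gte(rq_per$det, 95)

  set.seed(11)
  iid <- rr_series(rnorm(200, 800, 50))
  rq_iid <- hrv_rqa(iid, m = 2, tau = 1)
  expect_lt(rq_iid$det, rq_per$det)

  # deterministic given fixed cfg + input
  expect_identical(glance(rq_per), glance(hrv_rqa(per, m = 2, tau = 1)))
})

test_that("hrv_rqa derives its embedding from the series when unspecified", {
  rr <- synth_rr(cohort_spec("healthy"), duration = 300, seed = 2)
  out <- suppressWarnings(hrv_rqa(rr))
  expect_true(is.finite(out$settings$m))
  expect_true(is.finite(out$settings$tau))
  expect_true(out$rec >= 0 && out$rec <= 100)
})
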