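test_that("mse follows its definition and invariances", {
  expect_equal(mse(c(800, 810, 820), c(800, 810, 820)), 0)
  expect_equal(mse(c(800, 810, 820), c(801, 808, 823)), 14 / 3)
  x <- random_rr(50, 1); y <- random_rr(50, 2)
  expect_equal(mse(x + 7, y + 7), mse(x, y), tolerance = 1e-9)
  expect_error(mse(1:3, 1:4), class = "hrv_validation_error")
})

test_that("relative error compares series means in percent", {
  expect_equal(relative_error(c(800, 810, 820), c(800, 810, 820)), 0)
  x <- c(800, 810, 820)           # mean 810
  y <- c(801, 808, 823)           # mean 810.6667
  expect_equal(relative_error(x, y), 100 * abs(810 - 2432 / 3) / 810,
               tolerance = 1e-9)
  expect_equal(round(relative_error(x, y), 4), 0.0823)
  expect_equal(relative_error(3 * x, 3 * y), relative_error(x, y),
               tolerance = 1e-12)
  expect_error(relative_error(c(-1, 1), c(1, 2)),
               class = "hrv_validation_error")
})

test_that("identical groups give t = 0, p = 1", {
  df <- data.frame(v = rep(c(5, 6, 7), 2), g = rep(c("a", "b"), each = 3))
  cmp <- compare_groups(df, "v", "g")
  expect_equal(cmp$groups$p_t[cmp$groups$group == "b"], 1)
  expect_true(is.na(cmp$groups$p_t[cmp$groups$group == "a"]))
})

test_that("Welch t-test p-values match the closed-form oracle", {
  for (s in 1:25) {
    set.seed(700 + s)
    a <- rnorm(sample(5:15, 1), mean = 10, sd = 2)
    b <- rnorm(sample(5:15, 1), mean = 10 + runif(1, -2, 2), sd = 3)
    df <- data.frame(v = c(a, b),
                     g = rep(c("a", "b"), c(length(a), length(b))))
    cmp <- compare_groups(df, "v", "g", reference = "a")
    expect_lt(abs(cmp$groups$p_t[2] - oracle_welch_t(a, b)$p), 1e-9)
  }
})

test_that("two-group ANOVA equals the squared pooled t-test", {
  set.seed(99)
  df <- data.frame(v = c(rnorm(12, 10), rnorm(9, 11)),
                   g = rep(c("a", "b"), c(12, 9)))
  cmp <- compare_groups(df, "v", "g", var_equal = TRUE)
  # with equal variances assumed, F = t^2 so the p-values coincide
  expect_lt(abs(cmp$p_anova - cmp$groups$p_t[2]), 1e-6)
})

test_that("degenerate inputs are handled with warnings", {
  df0 <- data.frame(v = rep(4, 8), g = rep(c("a", "b"), each = 4))
  expect_warning(cmp <- compare_groups(df0, "v", "g"), "ANOVA")
  expect_true(is.na(cmp$p_anova))
  expect_equal(cmp$groups$p_t[2], 1)  # identical constants: no difference
  expect_error(compare_groups(data.frame(v = 1:4, g = c("a", "a", "a", "b")),
                              "v", "g"),
               class = "hrv_validation_error")
})

test_that("cohort tables have the clinical-table layout", {
  recs <- c(lapply(1:3, function(s)
              synth_rr(cohort_spec("healthy"), 120, seed = s)),
            lapply(4:6, function(s)
              synth_rr(cohort_spec("syncope"), 120, seed = s)))
  tab <- suppressWarnings(
    hrv_cohort(recs, groups = rep(c("healthy", "syncope"), each = 3),
               rqa_m = 3, rqa_tau = 1, seg_len = 128))
  expect_s3_class(tab, "hrv_cohort_table")
  expect_true(all(c("parameter", "mean_healthy", "sd_healthy",
                    "mean_syncope", "sd_syncope", "p_t_syncope",
                    "p_anova") %in% names(tab)))
  expect_true(all(c("rmssd", "sd1", "det", "lf_nu") %in% tab$parameter))
  expect_false("p_t_healthy" %in% names(tab))  # reference has no t column

  single <- suppressWarnings(
    hrv_cohort(recs[1:3], groups = rep("healthy", 3),
               rqa_m = 3, rqa_tau = 1, seg_len = 128))
  expect_true(all(is.na(single$p_anova)))
  expect_false(any(grepl("^p_t_", names(single))))
})

test_that("tidiers return well-formed tibbles", {
  rr <- synth_rr(cohort_spec("healthy"), 120, seed = 2)
  td <- suppressWarnings(hrv_time(rr))
  expect_named(tidy(td), c("parameter", "value"))
  p <- hrv_poincare(rr)
  expect_named(glance(p), c("sd1", "sd2", "ratio", "n_points"))
  expect_equal(nrow(tidy(p)), nrow(rr) - 1)
  rq <- hrv_rqa(rr, m = 3, tau = 1)
  expect_true(all(c("rec", "det", "lam", "entr") %in% names(glance(rq))))
})
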