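#' Mean squared error between two equal-length series
#'
#' \eqn{MSE = (1/N) \sum_i (x_i - y_i)^2}, the device-validation error
#' between a reference interval series and a test series.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The MSE, in squared input units.
#' @examples
#' mse(c(800, 810, 820), c(801, 808, 823))
#' @export
mse <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(length(x) >= 1L, "series must be non-empty")
  mean((x - y)^2)
}

#' Relative error between series means
#'
#' `100 * |mean(x) - mean(y)| / mean(x)`, in percent — the between-device
#' agreement measure for mean beat counts / interval lengths.
#'
#' @param x Reference series (mean must be nonzero).
#' @param y Test series.
#' @return Relative error in percent.
#' @export
relative_error <- function(x, y) {
  assert_that(mean(x) != 0, "reference mean is zero")
  100 * abs(mean(x) - mean(y)) / mean(x)
}

#' Compare one parameter across groups
#'
#' Tidy group comparison of a single numeric parameter: per-group mean, sd
#' and n; a two-sided two-sample t-test of the reference group against every
#' other group (Welch by default); and a one-way ANOVA across all groups.
#'
#' @param data A data frame with one row per observation.
#' @param value Column name (string) of the parameter values.
#' @param group Column name (string) of the group labels.
#' @param reference Reference group label (default: first group in order of
#'   appearance).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A list of class `group_comparison`: `groups` (tibble `group`,
#'   `mean`, `sd`, `n`, `p_t` — `NA` for the reference), `p_anova`,
#'   `reference`, `parameter`.
#' @examples
#' df <- data.frame(v = c(1:5, 2:6), g = rep(c("a", "b"), each = 5))
#' compare_groups(df, "v", "g")$p_anova
#' @export
compare_groups <- function(data, value, group, reference = NULL,
                           var_equal = FALSE) {
  assert_that(is.data.frame(data), "data must be a data frame")
  assert_that(all(c(value, group) %in% names(data)),
              "value/group columns not found in data")
  v <- data[[value]]
  g <- as.character(data[[group]])
  ok <- is.finite(v)
  v <- v[ok]; g <- g[ok]
  levels <- unique(g)
  assert_that(length(levels) >= 1L, "no groups present")
  counts <- table(g)
  assert_that(all(counts >= 2L), "every group needs n >= 2")
  reference <- reference %||% levels[1]
  assert_that(reference %in% levels, "reference group not present")

  groups <- tibble::tibble(
    group = levels,
    mean = vapply(levels, function(l) mean(v[g == l]), numeric(1),
                  USE.NAMES = FALSE),
    sd = vapply(levels, function(l) sd(v[g == l]), numeric(1),
                USE.NAMES = FALSE),
    n = vapply(levels, function(l) sum(g == l), integer(1),
               USE.NAMES = FALSE),
    p_t = vapply(levels, function(l) {
      if (l == reference) return(NA_real_)
      a <- v[g == reference]; b <- v[g == l]
      if (sd(a) == 0 && sd(b) == 0) {
        if (mean(a) == mean(b)) return(1) else return(0)
      }
      t.test(a, b, var.equal = var_equal)$p.value
    }, numeric(1), USE.NAMES = FALSE)
  )
  p_anova <- if (length(levels) >= 2L) {
    if (all(groups$sd == 0)) {
      warn("zero within-group variance in every group: ANOVA undefined")
      NA_real_
    } else {
      fit <- aov(v ~ factor(g))
      summary(fit)[[1]][["Pr(>F)"]][1]
    }
  } else NA_real_
  structure(list(groups = groups, p_anova = p_anova,
                 reference = reference, parameter = value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s (reference %s), ANOVA p = %s>\n",
              x$parameter, x$reference,
              if (is.na(x$p_anova)) "NA" else format(x$p_anova, digits = 4)))
  print(x$groups)
  invisible(x)
}

#' Full cohort HRV comparison table
#'
#' Runs the time-domain, spectral, Poincaré and recurrence analyses on every
#' record, aggregates per group, and emits one row per HRV parameter with
#' per-group mean ± sd, a t-test p-value for each non-reference group
#' against the reference, and a one-way ANOVA p-value across groups — the
#' layout of a clinical cohort comparison table.
#'
#' @param records A data frame with a list-column `rr` of [rr_series()]
#'   objects and a `group` column, or a list of rr_series plus a `groups`
#'   vector.
#' @param groups Group label per record (if `records` is a bare list).
#' @param reference Reference group (default first).
#' @param rqa_m,rqa_tau,rqa_epsilon_frac Fixed RQA embedding settings used
#'   for every record, so recurrence measures are comparable across groups.
#' @param seg_len Welch segment length (samples at 4 Hz).
#' @param var_equal Pooled-variance t-tests instead of Welch.
#' @return A tibble of class `hrv_cohort_table`: one row per parameter with
#'   columns `parameter`, then `mean_<group>`, `sd_<group>`, `p_t_<group>`
#'   per group, and `p_anova`. Attribute `"n_failed"` counts records whose
#'   analysis failed (they are excluded with a warning).
#' @examples
#' recs <- lapply(1:4, function(s)
#'   synth_rr(cohort_spec(if (s <= 2) "healthy" else "syncope"),
#'            duration = 120, seed = s))
#' tab <- hrv_cohort(recs, groups = rep(c("healthy", "syncope"), each = 2),
#'                   rqa_m = 3, rqa_tau = 1)
#' @export
hrv_cohort <- function(records, groups = NULL, reference = NULL,
                       rqa_m = 3, rqa_tau = 1, rqa_epsilon_frac = 0.1,
                       seg_len = 256, var_equal = FALSE) {
  if (is.data.frame(records)) {
    groups <- groups %||% records$group
    records <- records$rr
  }
  assert_that(is.list(records) && length(records) >= 2L,
              "need at least two records")
  assert_that(length(groups) == length(records),
              "one group label per record is required")
  groups <- as.character(groups)

  one_record <- function(rr) {
    td <- hrv_time(rr)
    geo <- geometric_indices(rr_histogram(rr))
    sp <- hrv_frequency(rr, seg_len = seg_len)$bands
    pc <- hrv_poincare(rr)
    rq <- hrv_rqa(rr, m = rqa_m, tau = rqa_tau,
                  epsilon_frac = rqa_epsilon_frac)
    tibble::tibble(
      mean_rr = td$mean_rr, sdnn = td$sdnn, sdann = td$sdann,
      rmssd = td$rmssd, sdnn_index = td$sdnn_index, pnn50 = td$pnn50,
      hrv_ti = geo$hrv_ti, tinn = geo$tinn,
      vlf_power = sp$vlf_power, lf_power = sp$lf_power,
      hf_power = sp$hf_power, lf_nu = sp$lf_nu, hf_nu = sp$hf_nu,
      lf_hf = sp$lf_hf,
      sd1 = pc$sd1, sd2 = pc$sd2, sd1_sd2 = pc$ratio,
      rec = rq$rec, det = rq$det, lam = rq$lam, entr = rq$entr
    )
  }

  rows <- vector("list", length(records))
  failed <- 0L
  for (i in seq_along(records)) {
    rows[[i]] <- tryCatch(
      suppressWarnings(one_record(records[[i]])),
      error = function(e) {
        warn(sprintf("record %d failed and was excluded: %s",
                     i, conditionMessage(e)))
        NULL
      })
    if (is.null(rows[[i]])) failed <- failed + 1L
  }
  keep <- !vapply(rows, is.null, logical(1))
  per_rec <- dplyr::bind_rows(rows[keep])
  per_rec$group <- groups[keep]

  params <- setdiff(names(per_rec), "group")
  levels <- unique(per_rec$group)
  reference <- reference %||% levels[1]
  single_group <- length(levels) < 2L

  out <- purrr::map_dfr(params, function(p) {
    row <- tibble::tibble(parameter = p)
    if (single_group) {
      l <- levels[1]
      row[[paste0("mean_", l)]] <- mean(per_rec[[p]][per_rec$group == l])
      row[[paste0("sd_", l)]] <- sd(per_rec[[p]][per_rec$group == l])
      row[["p_anova"]] <- NA_real_
      return(row)
    }
    enough <- all(vapply(levels, function(l)
      sum(is.finite(per_rec[[p]][per_rec$group == l])), integer(1)) >= 2L)
    cmp <- if (enough) {
      compare_groups(per_rec, p, "group", reference = reference,
                     var_equal = var_equal)
    } else NULL
    for (l in levels) {
      vl <- per_rec[[p]][per_rec$group == l]
      row[[paste0("mean_", l)]] <- mean(vl, na.rm = TRUE)
      row[[paste0("sd_", l)]] <- sd(vl[is.finite(vl)])
      if (l != reference) {
        row[[paste0("p_t_", l)]] <- if (is.null(cmp)) NA_real_ else
          cmp$groups$p_t[cmp$groups$group == l]
      }
    }
    row[["p_anova"]] <- if (is.null(cmp)) NA_real_ else cmp$p_anova
    row
  })
  attr(out, "n_failed") <- failed
  attr(out, "reference") <- reference
  class(out) <- c("hrv_cohort_table", class(out))
  out
}
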