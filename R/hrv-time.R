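#' Time-domain and segment HRV indices
#'
#' Computes the conventional (Task Force) time-domain indices of an NN
#' interval series:
#' * `mean_rr` — arithmetic mean of the intervals (ms);
#' * `sdnn` — sample (n-1) standard deviation of all intervals (ms);
#' * `sdann` — sd of the mean interval of consecutive, non-overlapping
#'   `segment_seconds` windows (default 5 min), incomplete tail dropped;
#' * `sdnn_index` — mean of the per-segment sds;
#' * `rmssd` — root mean square of successive differences (ms);
#' * `pnn50` — percentage of successive differences exceeding 50 ms.
#'
#' Segments are formed on beat time: an interval belongs to the window
#' containing the beat that opens it. `sdann` and `sdnn_index` are `NA`
#' unless at least two complete segments are available.
#'
#' @param rr An [rr_series()]; a warning is issued if it is not NN-filtered.
#' @param segment_seconds Segment length for SDANN/SDNN index (default 300).
#' @param pnn_threshold Threshold for pNN50 in ms (default 50).
#' @return A one-row tibble of class `hrv_time_report` with the fields above
#'   plus `n_intervals` and `segment_count`.
#' @examples
#' rr <- rr_series(c(800, 810, 800, 810), is_nn = TRUE)
#' hrv_time(rr)$rmssd
#' @export
hrv_time <- function(rr, segment_seconds = 300, pnn_threshold = 50) {
  validate_rr_series(rr)
  if (!is_nn(rr)) {
    warn("rr series is not NN-filtered; time-domain indices assume NN intervals")
  }
  iv <- rr$rr
  n <- length(iv)
  assert_that(n >= 2L, "time-domain analysis needs at least 2 intervals")
  d <- diff(iv)

  onset <- head(beat_times(rr), n) - rr_t0(rr)
  total <- rr$time[n] - rr_t0(rr)
  seg <- floor(onset / segment_seconds)
  n_complete <- floor(total / segment_seconds)
  keep <- seg < n_complete
  seg_stats <- if (n_complete >= 2L) {
    means <- tapply(iv[keep], seg[keep], mean)
    sds <- tapply(iv[keep], seg[keep], sd)
    list(sdann = sd(means), sdnn_index = mean(sds, na.rm = TRUE),
         count = as.integer(n_complete))
  } else {
    list(sdann = NA_real_, sdnn_index = NA_real_,
         count = as.integer(n_complete))
  }

  out <- tibble::tibble(
    mean_rr = mean(iv),
    sdnn = sd(iv),
    sdann = seg_stats$sdann,
    rmssd = sqrt(mean(d^2)),
    sdnn_index = seg_stats$sdnn_index,
    pnn50 = 100 * sum(abs(d) > pnn_threshold) / length(d),
    n_intervals = n,
    segment_count = seg_stats$count
  )
  class(out) <- c("hrv_time_report", class(out))
  out
}

#' RR interval histogram
#'
#' Uniform-bin histogram of the interval lengths, bins aligned to 0. The
#' default bin width is 7.8125 ms (1/128 s), the standard discretization for
#' the geometric indices.
#'
#' @param rr An [rr_series()].
#' @param bin_width Bin width in ms (> 0).
#' @return A list of class `rr_histogram` with `breaks` (bin edges, ms),
#'   `counts`, `mids` and `mode_bin` (index of the tallest bin).
#' @export
rr_histogram <- function(rr, bin_width = 7.8125) {
  validate_rr_series(rr)
  assert_that(is_number(bin_width) && bin_width > 0, "bin_width must be > 0")
  iv <- rr$rr
  lo <- floor(min(iv) / bin_width) * bin_width
  hi <- ceiling(max(iv) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  # right-open bins [a, b): shift by tiny epsilon via findInterval
  idx <- pmin(findInterval(iv, breaks), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(
    breaks = breaks,
    counts = counts,
    mids = (head(breaks, -1) + tail(breaks, -1)) / 2,
    mode_bin = which.max(counts),
    bin_width = bin_width,
    n_intervals = length(iv)
  ), class = "rr_histogram")
}

#' Geometric HRV indices (triangular index and TINN)
#'
#' `hrv_ti` is the total interval count divided by the modal bin count.
#' `tinn` is the base width `M - N` of the triangle best fitting the
#' histogram: a brute-force search over bin-edge pairs `N < mode < M` of the
#' triangle that is zero outside `[N, M]`, peaks at the mode bin center with
#' the observed mode height, minimizing the squared error against the bin
#' counts.
#'
#' @param hist An [rr_histogram()].
#' @return A one-row tibble with `hrv_ti`, `tinn` (ms), `tinn_n`, `tinn_m`.
#' @export
geometric_indices <- function(hist) {
  assert_that(inherits(hist, "rr_histogram"), "expected an rr_histogram")
  counts <- hist$counts
  assert_that(any(counts > 0), "histogram has no nonzero bin")
  total <- sum(counts)
  peak <- max(counts)
  mode_i <- hist$mode_bin
  hrv_ti <- total / peak
  nz <- which(counts > 0)
  if (length(nz) == 1L) {
    return(tibble::tibble(hrv_ti = 1, tinn = 0,
                          tinn_n = hist$breaks[nz],
                          tinn_m = hist$breaks[nz + 1L]))
  }
  mids <- hist$mids
  edges <- hist$breaks
  peak_x <- mids[mode_i]
  n_cand <- edges[edges < peak_x]
  m_cand <- edges[edges > peak_x]
  best <- list(err = Inf, n = NA_real_, m = NA_real_)
  for (N in n_cand) {
    up <- ifelse(mids <= peak_x & mids >= N,
                 peak * (mids - N) / (peak_x - N), NA_real_)
    for (M in m_cand) {
      tri <- ifelse(mids > peak_x,
                    ifelse(mids <= M, peak * (M - mids) / (M - peak_x), 0),
                    ifelse(is.na(up), 0, up))
      err <- sum((counts - tri)^2)
      if (err < best$err) best <- list(err = err, n = N, m = M)
    }
  }
  tibble::tibble(hrv_ti = hrv_ti, tinn = best$m - best$n,
                 tinn_n = best$n, tinn_m = best$m)
}
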