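#' Recurrence matrix of a delay-embedded series
#'
#' Embeds the scalar series with dimension `m` and delay `tau` and marks
#' every pair of state vectors closer than `epsilon` as recurrent:
#' `R[i, j] = 1` iff `dist(v_i, v_j) <= epsilon`. The matrix is symmetric
#' with an all-ones main diagonal (line of identity).
#'
#' @param x Numeric series.
#' @param m Embedding dimension (>= 1).
#' @param tau Embedding delay in samples (>= 1).
#' @param epsilon Recurrence threshold (> 0), in the units of `x`.
#' @param norm Distance norm: `"euclidean"` or `"max"` (Chebyshev).
#' @return A logical matrix of size `n - (m-1) tau` squared.
#' @export
recurrence_matrix <- function(x, m = 1L, tau = 1L, epsilon,
                              norm = c("euclidean", "max")) {
  norm <- match.arg(norm)
  x <- as.numeric(x)
  m <- as.integer(m); tau <- as.integer(tau)
  assert_that(m >= 1L && tau >= 1L, "m and tau must be >= 1")
  assert_that(is_number(epsilon) && epsilon > 0, "epsilon must be > 0")
  np <- length(x) - (m - 1L) * tau
  assert_that(np >= 2L, "series too short for this embedding")
  emb <- embed_series(x, m, tau)
  d <- embed_dist(emb, norm)
  d <= epsilon
}

embed_series <- function(x, m, tau) {
  np <- length(x) - (m - 1L) * tau
  vapply(0:(m - 1L), function(k) x[(1:np) + k * tau], numeric(np))
}

embed_dist <- function(emb, norm) {
  emb <- as.matrix(emb)
  if (norm == "euclidean") {
    as.matrix(stats::dist(emb))
  } else {
    np <- nrow(emb)
    d <- matrix(0, np, np)
    for (k in seq_len(ncol(emb))) {
      d <- pmax(d, abs(outer(emb[, k], emb[, k], "-")))
    }
    d
  }
}

#' Recurrence quantification (REC, DET, LAM, ENTR)
#'
#' Quantifies a recurrence matrix, always excluding the line of identity
#' (LOI):
#' * `rec` — recurrence rate: 100 x (recurrent points off the LOI) /
#'   (N^2 - N);
#' * `det` — determinism: percentage of those points lying on diagonal
#'   lines of length >= `l_min`;
#' * `lam` — laminarity: percentage lying on vertical runs of length >=
#'   `v_min` (the matrix is symmetric, so vertical and horizontal counts
#'   coincide);
#' * `entr` — Shannon entropy (nats) of the distribution of diagonal line
#'   lengths >= `l_min`.
#'
#' @param rm Logical (or 0/1) square symmetric recurrence matrix.
#' @param l_min Minimum diagonal line length (default 2).
#' @param v_min Minimum vertical run length (default 2).
#' @return A list of class `hrv_rqa` with `rec`, `det`, `lam`, `entr`,
#'   `diag_hist` and `vert_hist` (tibbles `length`, `count`), `n_points`,
#'   and `settings`.
#' @export
rqa <- function(rm, l_min = 2L, v_min = 2L) {
  rm <- as.matrix(rm) != 0
  N <- nrow(rm)
  assert_that(N == ncol(rm), "recurrence matrix must be square")
  assert_that(all(rm == t(rm)), "recurrence matrix must be symmetric")
  diag(rm) <- FALSE  # exclude the line of identity from all counts
  n_rec <- sum(rm)
  rec <- 100 * n_rec / (N^2 - N)

  # diagonal maximal runs over every off-main diagonal (both triangles)
  diag_lengths <- integer(0)
  for (k in seq_len(N - 1L)) {
    v <- rm[cbind(seq_len(N - k), seq_len(N - k) + k)]
    r <- run_lengths_true(v)
    if (length(r)) diag_lengths <- c(diag_lengths, r, r)  # symmetric copy
  }
  # vertical maximal runs per column (LOI already removed)
  vert_lengths <- integer(0)
  for (j in seq_len(N)) {
    r <- run_lengths_true(rm[, j])
    if (length(r)) vert_lengths <- c(vert_lengths, r)
  }

  if (n_rec == 0L) {
    det <- NA_real_; lam <- NA_real_; entr <- NA_real_
  } else {
    det <- 100 * sum(diag_lengths[diag_lengths >= l_min]) / n_rec
    lam <- 100 * sum(vert_lengths[vert_lengths >= v_min]) / n_rec
    dl <- diag_lengths[diag_lengths >= l_min]
    entr <- if (length(dl)) {
      p <- table(dl) / length(dl)
      -sum(p * log(p))
    } else NA_real_
  }
  structure(list(
    rec = rec, det = det, lam = lam, entr = entr,
    diag_hist = length_hist(diag_lengths, l_min),
    vert_hist = length_hist(vert_lengths, v_min),
    n_points = N,
    settings = list(l_min = l_min, v_min = v_min)
  ), class = "hrv_rqa")
}

length_hist <- function(lengths, min_len) {
  lengths <- lengths[lengths >= min_len]
  if (!length(lengths)) {
    return(tibble::tibble(length = integer(0), count = integer(0)))
  }
  tab <- table(lengths)
  tibble::tibble(length = as.integer(names(tab)),
                 count = as.integer(tab))
}

#' Recurrence quantification of an RR series
#'
#' Embeds the interval series and runs [recurrence_matrix()] +
#' [rqa()]. If `m` or `tau` are `NULL` they are estimated from the series
#' itself via [fnn()] and [ami()]. The threshold is `epsilon_frac` times the
#' maximum pairwise embedded distance (phase-space extent); a fixed
#' `epsilon` can be given instead.
#'
#' @param rr An [rr_series()] with at least 50 intervals.
#' @param m,tau Embedding dimension and delay; `NULL` = estimate.
#' @param epsilon_frac Threshold as a fraction of the maximum pairwise
#'   distance (default 0.1); ignored when `epsilon` is given.
#' @param epsilon Optional fixed threshold in ms.
#' @param norm Distance norm (see [recurrence_matrix()]).
#' @param l_min,v_min Minimum diagonal / vertical line lengths.
#' @return An `hrv_rqa` (see [rqa()]) whose `settings` also record
#'   `m`, `tau`, `epsilon` and `norm`.
#' @examples
#' rr <- synth_rr(cohort_spec("healthy"), duration = 120, seed = 1)
#' hrv_rqa(rr, m = 3, tau = 1)$rec
#' @export
hrv_rqa <- function(rr, m = NULL, tau = NULL, epsilon_frac = 0.1,
                    epsilon = NULL, norm = "euclidean",
                    l_min = 2L, v_min = 2L) {
  validate_rr_series(rr)
  iv <- rr$rr
  assert_that(length(iv) >= 50L, "RQA needs at least 50 intervals")
  if (is.null(tau)) {
    tau <- ami(iv, tau_max = min(30L, length(iv) %/% 4L))$tau_opt
  }
  if (is.null(m)) {
    m <- fnn(iv, tau = tau, m_max = 8L)$m_opt
    if (is.na(m)) m <- 3L
  }
  emb <- embed_series(iv, as.integer(m), as.integer(tau))
  d <- embed_dist(emb, match.arg(norm, c("euclidean", "max")))
  if (is.null(epsilon)) epsilon <- epsilon_frac * max(d)
  assert_that(epsilon > 0, "epsilon must be > 0")
  out <- rqa(d <= epsilon, l_min = l_min, v_min = v_min)
  out$settings <- c(out$settings,
                    list(m = m, tau = tau, epsilon = epsilon, norm = norm))
  out
}

#' @export
print.hrv_rqa <- function(x, ...) {
  cat(sprintf("<hrv_rqa: REC %.1f%%  DET %.1f%%  LAM %.1f%%  ENTR %.3f (N = %d)>\n",
              x$rec, x$det, x$lam, x$entr, x$n_points))
  invisible(x)
}
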