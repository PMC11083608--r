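#' Average mutual information and optimal delay
#'
#' Estimates, for every lag `tau` in `0..tau_max`, the mutual information
#' (nats) between `x(t)` and `x(t + tau)` from a 2-D histogram with `bins`
#' equal-width bins per axis (shared breaks from the full series range). The
#' optimal embedding delay `tau_opt` is the first local minimum of the
#' curve, judged over a neighborhood of `min_window` lags on each side so
#' that single-lag ripple of the histogram estimator does not trigger a
#' spurious early minimum; if no local minimum exists the global minimum
#' is returned with a warning. At lag 0 the curve equals the marginal
#' entropy estimate.
#'
#' @param x Numeric series.
#' @param tau_max Largest lag to evaluate.
#' @param bins Histogram bins per axis (default 16).
#' @param min_window Neighborhood half-width (lags) for the first-minimum
#'   search (default 2; 1 reproduces the strict three-point rule).
#' @return A list of class `hrv_ami` with `curve` (tibble `tau`, `ami`) and
#'   `tau_opt`.
#' @export
ami <- function(x, tau_max = 30L, bins = 16L, min_window = 2L) {
  x <- as.numeric(x)
  tau_max <- as.integer(tau_max)
  assert_that(length(x) > tau_max + 10L, "series too short for tau_max")
  rng <- range(x)
  assert_that(rng[2] > rng[1], "AMI is undefined for a constant series")
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  cuts <- findInterval(x, breaks, rightmost.closed = TRUE)
  cuts <- pmin(pmax(cuts, 1L), bins)
  vals <- vapply(0:tau_max, function(tau) {
    a <- cuts[seq_len(length(x) - tau)]
    b <- cuts[seq_len(length(x) - tau) + tau]
    joint <- table(factor(a, levels = 1:bins), factor(b, levels = 1:bins))
    p <- joint / sum(joint)
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  }, numeric(1))
  curve <- tibble::tibble(tau = 0:tau_max, ami = vals)
  w <- max(1L, as.integer(min_window))
  tau_opt <- NA_integer_
  for (k in seq_len(tau_max - 1L)) {  # lag k at vals[k + 1]
    lo <- max(0L, k - w)
    hi <- min(tau_max, k + w)
    nbrs <- setdiff(lo:hi, k)
    if (vals[k + 1L] < vals[k] && all(vals[k + 1L] <= vals[nbrs + 1L])) {
      tau_opt <- k
      break
    }
  }
  if (is.na(tau_opt)) {
    warn("no local minimum of AMI found; using the global minimum lag")
    tau_opt <- which.min(vals[-1L])
  }
  structure(list(curve = curve, tau_opt = as.integer(tau_opt)),
            class = "hrv_ami")
}

#' False nearest neighbors and optimal embedding dimension
#'
#' For each dimension `m` in `1..m_max`, embeds the series with delay
#' `tau`, finds each point's nearest neighbor (excluding a Theiler window
#' of `tau` samples in time and zero-distance duplicates, which fall back
#' to the next-nearest neighbor), and flags the neighbor as false when the
#' added `(m+1)`-th coordinate either grows the distance by more than
#' `rtol` relative to the current distance or pushes the expanded distance
#' beyond `atol` times the series sd (Kennel criteria). The optimal
#' dimension `m_opt` is the first with a false-neighbor percentage at or
#' below `threshold_pct`.
#'
#' @param x Numeric series.
#' @param tau Embedding delay (>= 1).
#' @param m_max Largest dimension to evaluate.
#' @param rtol Relative distance-growth threshold (default 15).
#' @param atol Absolute threshold in units of the series sd (default 2).
#' @param threshold_pct FNN percentage defining `m_opt` (default 1).
#' @return A list of class `hrv_fnn` with `curve` (tibble `m`, `fnn_pct`)
#'   and `m_opt`. If the curve never crosses the threshold (typical for
#'   strongly stochastic series with no low-dimensional structure), the
#'   dimension of the curve minimum is returned with a warning.
#' @export
fnn <- function(x, tau, m_max = 8L, rtol = 15, atol = 2,
                threshold_pct = 1) {
  x <- as.numeric(x)
  tau <- as.integer(tau); m_max <- as.integer(m_max)
  assert_that(tau >= 1L, "tau must be >= 1")
  assert_that(length(x) > m_max * tau + 10L, "series too short for m_max")
  sdx <- sd(x)
  assert_that(sdx > 0, "FNN is undefined for a constant series")
  pct <- numeric(m_max)
  for (m in seq_len(m_max)) {
    np <- length(x) - m * tau  # points that admit the (m+1)-th coordinate
    emb <- embed_series(x[seq_len(length(x) - tau)], m, tau)[seq_len(np), ,
                                                             drop = FALSE]
    d <- as.matrix(stats::dist(emb))
    # Theiler exclusion + self
    for (off in 0:tau) {
      idx <- seq_len(np - off)
      d[cbind(idx, idx + off)] <- Inf
      d[cbind(idx + off, idx)] <- Inf
    }
    d[d <= 1e-8 * sdx] <- Inf  # duplicates (to float tolerance): next-nearest
    nn <- apply(d, 1L, which.min)
    rd <- d[cbind(seq_len(np), nn)]
    usable <- is.finite(rd)
    extra <- abs(x[seq_len(np) + m * tau] - x[nn + m * tau])
    expanded <- sqrt(rd^2 + extra^2)
    false_nb <- (extra / rd > rtol) | (expanded / sdx > atol)
    pct[m] <- 100 * sum(false_nb[usable]) / max(1L, sum(usable))
  }
  curve <- tibble::tibble(m = seq_len(m_max), fnn_pct = pct)
  hit <- which(pct <= threshold_pct)
  m_opt <- if (length(hit)) hit[1] else {
    warn(paste("FNN never fell below the threshold;",
               "using the dimension of the curve minimum"))
    which.min(pct)
  }
  structure(list(curve = curve, m_opt = as.integer(m_opt)),
            class = "hrv_fnn")
}

#' Three-dimensional delay-embedded attractor
#'
#' Exports the triples `(x(t), x(t + tau), x(t + 2 tau))` for plotting the
#' reconstructed phase-space attractor.
#'
#' @param x Numeric series with `length(x) > 2 * tau`.
#' @param tau Embedding delay (>= 1).
#' @return A tibble with `n - 2 tau` rows and columns `x`, `y`, `z`.
#' @export
attractor3d <- function(x, tau) {
  x <- as.numeric(x)
  tau <- as.integer(tau)
  assert_that(tau >= 1L, "tau must be >= 1")
  n <- length(x)
  assert_that(n > 2L * tau, "series too short for a 3-D embedding")
  np <- n - 2L * tau
  a <- x[seq_len(np)]
  b <- x[seq_len(np) + tau]
  c_ <- x[seq_len(np) + 2L * tau]
  tibble::tibble(x = a, y = b, z = c_)
}

#' Phase-space reconstruction diagnostics for an RR series
#'
#' Runs [ami()] (delay), [fnn()] at the chosen delay (dimension) and
#' [attractor3d()] on the interval series.
#'
#' @param rr An [rr_series()].
#' @param tau_max,bins Passed to [ami()].
#' @param m_max,rtol,atol,threshold_pct Passed to [fnn()].
#' @return A list of class `hrv_embedding` with `ami_curve`, `tau_opt`,
#'   `fnn_curve`, `m_opt` and `attractor` (tibble `x`, `y`, `z`).
#' @examples
#' rr <- synth_rr(cohort_spec("healthy"), duration = 300, seed = 1)
#' emb <- hrv_embedding(rr)
#' c(emb$tau_opt, emb$m_opt)
#' @export
hrv_embedding <- function(rr, tau_max = 30L, bins = 16L, m_max = 8L,
                          rtol = 15, atol = 2, threshold_pct = 1) {
  validate_rr_series(rr)
  iv <- rr$rr
  a <- ami(iv, tau_max = min(as.integer(tau_max), length(iv) %/% 4L),
           bins = bins)
  f <- fnn(iv, tau = a$tau_opt, m_max = m_max, rtol = rtol, atol = atol,
           threshold_pct = threshold_pct)
  structure(list(
    ami_curve = a$curve, tau_opt = a$tau_opt,
    fnn_curve = f$curve, m_opt = f$m_opt,
    attractor = attractor3d(iv, a$tau_opt)
  ), class = "hrv_embedding")
}

#' @export
print.hrv_embedding <- function(x, ...) {
  cat(sprintf("<hrv_embedding: tau_opt = %d, m_opt = %s (%d attractor points)>\n",
              x$tau_opt,
              if (is.na(x$m_opt)) "NA" else as.character(x$m_opt),
              nrow(x$attractor)))
  invisible(x)
}
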