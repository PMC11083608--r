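# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (direct formulas, brute-force scans)
# rather than calling the package's own implementation paths.

# FFT amplitude of component at frequency f (Hz) in a series sampled at fs.
amp_at <- function(x, fs, f) {
  n <- length(x)
  k <- round(f * n / fs) + 1
  2 * Mod(fft(x - mean(x))[k]) / n
}

# Direct-formula time-domain indices (independent of hrv_time internals).
oracle_time_domain <- function(iv, seg_s = 300) {
  d <- diff(iv)
  onset <- c(0, cumsum(iv) / 1000)[seq_along(iv)]
  total <- sum(iv) / 1000
  n_seg <- floor(total / seg_s)
  res <- list(
    mean_rr = sum(iv) / length(iv),
    sdnn = sqrt(sum((iv - mean(iv))^2) / (length(iv) - 1)),
    rmssd = sqrt(sum(d^2) / length(d)),
    pnn50 = 100 * sum(abs(d) > 50) / length(d)
  )
  if (n_seg >= 2) {
    seg <- floor(onset / seg_s)
    keep <- seg < n_seg
    means <- sds <- numeric(n_seg)
    for (s in 0:(n_seg - 1)) {
      v <- iv[keep & seg == s]
      means[s + 1] <- mean(v)
      sds[s + 1] <- sd(v)
    }
    res$sdann <- sd(means)
    res$sdnn_index <- mean(sds)
  } else {
    res$sdann <- NA_real_
    res$sdnn_index <- NA_real_
  }
  res
}

# Closed-form Welch two-sample t-test (two-sided).
oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Naive O(N^2) recurrence quantification: double-loop matrix build plus
# explicit run-length scans along every diagonal and column.
naive_rqa <- function(x, m, tau, eps, l_min = 2, v_min = 2) {
  np <- length(x) - (m - 1) * tau
  R <- matrix(FALSE, np, np)
  for (i in 1:np) for (j in 1:np) {
    s <- 0
    for (k in 0:(m - 1)) s <- s + (x[i + k * tau] - x[j + k * tau])^2
    R[i, j] <- sqrt(s) <= eps
  }
  diag(R) <- FALSE
  n_rec <- sum(R)
  dl <- integer(0)
  for (off in 1:(np - 1)) {
    run <- 0
    for (i in 1:(np - off)) {
      if (R[i, i + off]) run <- run + 1
      else { if (run > 0) dl <- c(dl, run, run); run <- 0 }
    }
    if (run > 0) dl <- c(dl, run, run)  # both triangles (symmetric)
  }
  vl <- integer(0)
  for (j in 1:np) {
    run <- 0
    for (i in 1:np) {
      if (R[i, j]) run <- run + 1
      else { if (run > 0) vl <- c(vl, run); run <- 0 }
    }
    if (run > 0) vl <- c(vl, run)
  }
  dk <- dl[dl >= l_min]
  ent <- if (length(dk)) { p <- table(dk) / length(dk); -sum(p * log(p)) } else NA_real_
  list(
    rec = 100 * n_rec / (np^2 - np),
    det = if (n_rec) 100 * sum(dl[dl >= l_min]) / n_rec else NA_real_,
    lam = if (n_rec) 100 * sum(vl[vl >= v_min]) / n_rec else NA_real_,
    entr = ent,
    diag_lengths = sort(dl[dl >= l_min]),
    vert_lengths = sort(vl[vl >= v_min])
  )
}

# Brute-force triangular-interpolation fit over all bin-edge pairs,
# written independently of geometric_indices().
oracle_tinn <- function(counts, edges) {
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  peak <- max(counts)
  px <- mids[which.max(counts)]
  best <- c(Inf, NA, NA)
  for (N in edges[edges < px]) for (M in edges[edges > px]) {
    tri <- numeric(length(mids))
    left <- mids >= N & mids <= px
    right <- mids > px & mids <= M
    tri[left] <- peak * (mids[left] - N) / (px - N)
    tri[right] <- peak * (M - mids[right]) / (M - px)
    err <- sum((counts - tri)^2)
    if (err < best[1]) best <- c(err, N, M)
  }
  best[3] - best[2]
}

# Build an rr_series directly from a vector (flagged as NN for index tests).
rr_of <- function(iv, nn = TRUE) rr_series(iv, is_nn = nn)

# Random plausible RR vectors for property tests.
random_rr <- function(n, seed) {
  set.seed(seed)
  pmax(300, rnorm(n, 850, 60))
}
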