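# Independent oracles used to check the production code paths.
# These deliberately avoid the package's internals: explicit DFT matrix
# products, lm()-based detrending and hand-written loops.

# Brute-force Welch cross-spectrum via an explicit DFT matrix.
oracle_welch <- function(x, y, fs, K = 5L) {
  N <- length(x)
  L <- floor(2 * N / (K + 1))
  hop <- L %/% 2L
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
  u <- sum(w^2)
  kk <- 0:(L %/% 2L)
  E <- exp(-2i * pi * outer(kk, 0:(L - 1)) / L)
  nf <- length(kk)
  sxx <- syy <- numeric(nf)
  sxy <- rep(0 + 0i, nf)
  idx <- seq_len(L)
  for (seg in 0:(K - 1L)) {
    i <- seg * hop + idx
    xs <- unname(stats::resid(stats::lm(x[i] ~ idx))) * w
    ys <- unname(stats::resid(stats::lm(y[i] ~ idx))) * w
    X <- as.vector(E %*% xs)
    Y <- as.vector(E %*% ys)
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + Conj(X) * Y
  }
  sc <- 1 / (K * fs * u)
  fold <- rep(2, nf)
  fold[1L] <- 1
  if (L %% 2L == 0L) fold[nf] <- 1
  list(freq = kk * fs / L,
       sxx = sxx * sc * fold,
       syy = syy * sc * fold,
       sxy = sxy * sc * fold)
}

# Hand-loop RMSSD / pNN50 on a fully valid RR series.
oracle_rmssd_pnn50 <- function(rr) {
  ss <- 0
  n50 <- 0L
  npair <- length(rr) - 1L
  for (k in seq_len(npair)) {
    d <- rr[k + 1L] - rr[k]
    ss <- ss + d^2
    if (abs(d) > 50) n50 <- n50 + 1L
  }
  list(rmssd = sqrt(ss / npair), pnn50 = 100 * n50 / npair)
}

# Quartile by linear interpolation between order statistics (type-7 rule),
# written out by hand.
oracle_quartile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Per-segment linearly detrended variance, the quantity the Welch
# autospectrum integrates to (up to window weighting).
oracle_segment_variance <- function(x, K = 5L) {
  N <- length(x)
  L <- floor(2 * N / (K + 1))
  hop <- L %/% 2L
  idx <- seq_len(L)
  mean(vapply(0:(K - 1L), function(seg) {
    d <- unname(stats::resid(stats::lm(x[seg * hop + idx] ~ idx)))
    mean(d^2)
  }, numeric(1)))
}

# Trapezoid integral of a one-sided spectrum over all its bins.
oracle_integrate <- function(freq, psd) {
  sum(diff(freq) * (head(psd, -1) + tail(psd, -1)) / 2)
}

# Build a valid constant beat series of n cycles (helper fixture).
make_constant_series <- function(n = 380, rr_ms = 800, sbp = 120, dbp = 75) {
  t <- (seq_len(n) - 1) * rr_ms / 1000
  new_beat_series(tibble::tibble(
    t_s = t, rr_ms = rep(rr_ms, n),
    sbp_mmhg = rep(sbp, n), dbp_mmhg = rep(dbp, n),
    map_mmhg = rep(dbp + (sbp - dbp) / 3, n),
    valid = rep(TRUE, n)
  ))
}
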