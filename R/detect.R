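#' Detect R peaks in a resting ECG
#'
#' A minimal Pan-Tompkins-style detector adequate for clean resting lead-II
#' ECG: band-pass 5-25 Hz (2nd-order Butterworth, zero-phase), squaring, a
#' 150 ms moving-average energy envelope, and an adaptive threshold at half
#' the rolling 2 s envelope maximum. Candidate detections closer than the
#' 250 ms physiological refractory period are merged (the larger envelope
#' wins), and each R time is then localized to the sample of maximum
#' band-passed amplitude within +/- 50 ms of the envelope peak (the
#' zero-phase filter keeps the R apex in place).
#'
#' @param ecg Numeric ECG samples (mV), or a `waveform_record` with an
#'   `ecg` channel.
#' @param fs Sampling rate in Hz (>= 250). Taken from the record if omitted.
#' @return A tibble with `t_s` (R times, s) and `quality` (per-beat envelope
#'   confidence in \[0, 1\]).
#' @export
detect_r_peaks <- function(ecg, fs = NULL) {
  x <- channel_vector(ecg, "ecg", fs)
  fs <- x$fs
  ecg <- x$v
  if (fs < 250) {
    stop_barosens("ECG sampling rate must be >= 250 Hz for R-peak detection",
                  "config_error")
  }
  n <- length(ecg)
  if (n / fs < 10) {
    stop_barosens("ECG must be at least 10 s long", "insufficient_data_error")
  }
  if (sd(ecg) < 1e-9 * max(1, abs(mean(ecg)))) {
    stop_barosens("ECG looks flat-lined (zero variance); check electrodes",
                  "signal_quality_error")
  }
  t0 <- x$t0
  bp <- signal::butter(2, c(5, 25) / (fs / 2), type = "pass")
  filt <- filtfilt_padded(bp, ecg, round(2 * fs))
  env <- moving_average(filt^2, max(1L, round(0.150 * fs)))

  # adaptive threshold: 0.5 x rolling 2-s envelope max, via block maxima
  thr <- 0.5 * rolling_block_max(env, round(2 * fs))
  refractory <- round(0.25 * fs)

  above <- env > thr
  # candidate = local maxima of the envelope above threshold
  cand <- which(above &
                  env >= c(-Inf, env[-n]) &
                  env > c(env[-1L], -Inf))
  if (!length(cand)) {
    stop_barosens("no QRS-like activity found above the adaptive threshold",
                  "signal_quality_error")
  }
  keep <- enforce_refractory(cand, env[cand], refractory)

  # localize R at the band-passed-amplitude maximum near each envelope peak
  # (the zero-phase filter keeps the R apex in place and smooths wideband
  # noise that would otherwise jitter a raw argmax)
  half <- round(0.050 * fs)
  half <- as.integer(half)
  r_idx <- vapply(as.integer(keep), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(filt[lo:hi]) - 1L
  }, integer(1))
  r_idx <- unique(r_idx)
  r_idx <- enforce_refractory(r_idx, filt[r_idx], refractory)
  qual <- pmin(1, env[r_idx] / pmax(thr[r_idx] * 2, .Machine$double.eps))
  tibble(t_s = t0 + (r_idx - 1L) / fs, quality = qual)
}

channel_vector <- function(x, channel, fs) {
  if (inherits(x, "waveform_record") || is.data.frame(x)) {
    if (!channel %in% names(x)) {
      stop_barosens(paste0("record has no '", channel, "' channel"),
                    "format_error")
    }
    fs <- fs %||% attr(x, "fs", exact = TRUE)
    if (is.null(fs)) stop_barosens("`fs` missing", "config_error")
    t0 <- attr(x, "t0", exact = TRUE) %||%
      (if ("t_s" %in% names(x)) x$t_s[1L] else 0)
    list(v = x[[channel]], fs = fs, t0 = t0)
  } else {
    if (is.null(fs)) stop_barosens("`fs` missing", "config_error")
    list(v = as.numeric(x), fs = fs, t0 = 0)
  }
}

# zero-phase filtering with mirror padding to suppress boundary transients
filtfilt_padded <- function(flt, x, pad) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(pad))
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  signal::filtfilt(flt, xp)[pad + seq_len(n)]
}

moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2L)) |>
    fill_na_edges(x)
}

fill_na_edges <- function(y, x) {
  y[is.na(y)] <- x[is.na(y)]
  y
}

# rolling max approximated by linear interpolation between 2-block maxima;
# smooth enough for an adaptive detector threshold and O(n)
rolling_block_max <- function(x, width) {
  n <- length(x)
  width <- max(2L, as.integer(width))
  starts <- seq(1L, n, by = width)
  mids <- pmin(n, starts + width %/% 2L)
  bm <- vapply(starts, function(s) max(x[s:min(n, s + width - 1L)]),
               numeric(1))
  if (length(bm) == 1L) return(rep(bm, n))
  approx(mids, bm, xout = seq_len(n), rule = 2L)$y
}

enforce_refractory <- function(idx, strength, refractory) {
  if (!length(idx)) return(idx)
  o <- order(idx)
  idx <- idx[o]; strength <- strength[o]
  keep <- idx[1L]; ks <- strength[1L]
  for (j in seq_along(idx)[-1L]) {
    last <- length(keep)
    if (idx[j] - keep[last] < refractory) {
      if (strength[j] > ks[last]) {
        keep[last] <- idx[j]; ks[last] <- strength[j]
      }
    } else {
      keep <- c(keep, idx[j]); ks <- c(ks, strength[j])
    }
  }
  keep
}

#' Extract per-cycle SBP, DBP and MAP from the arterial pressure waveform
#'
#' For each cardiac cycle `[t_k, t_{k+1})` delimited by successive R waves,
#' SBP is the waveform maximum and DBP the minimum over the half-open cycle
#' (the next beat's onset sample belongs to the next cycle), while MAP is
#' the time average of the waveform over the entire cycle (trapezoidal
#' integration divided by the cycle length, with linear interpolation at
#' the exact cycle boundaries). The last, incomplete cycle is dropped.
#' Cycles containing non-finite samples are flagged invalid, not removed.
#'
#' @param bp Numeric arterial pressure samples (mmHg), or a
#'   `waveform_record` with a `bp` channel.
#' @param fs Sampling rate in Hz. Taken from the record if omitted.
#' @param beats R-peak annotations from [detect_r_peaks()], or a numeric
#'   vector of beat times in seconds.
#' @return A tibble with one row per complete cycle: `t_s` (cycle onset),
#'   `sbp_mmhg`, `dbp_mmhg`, `map_mmhg`, `valid`.
#' @export
extract_pressure_beats <- function(bp, fs = NULL, beats) {
  x <- channel_vector(bp, "bp", fs)
  fs <- x$fs
  bp <- x$v
  t_beats <- if (is.numeric(beats)) beats else beats$t_s
  if (length(t_beats) < 2L) {
    stop_barosens("need at least 2 beats to form a cycle",
                  "insufficient_data_error")
  }
  t_samp <- x$t0 + (seq_along(bp) - 1L) / fs
  if (t_beats[1L] < t_samp[1L] - 1 / fs ||
      t_beats[length(t_beats)] > t_samp[length(t_samp)] + 1 / fs) {
    stop_barosens("beats extend beyond the pressure recording", "data_error")
  }
  n_cyc <- length(t_beats) - 1L
  sbp <- dbp <- mp <- rep(NA_real_, n_cyc)
  valid <- rep(FALSE, n_cyc)
  for (k in seq_len(n_cyc)) {
    lo <- t_beats[k]; hi <- t_beats[k + 1L]
    # first sample with t >= lo, last with t <= hi (t = t0 + (i-1)/fs)
    i0 <- as.integer(ceiling((lo - x$t0) * fs - 1e-9)) + 1L
    i1 <- as.integer(floor((hi - x$t0) * fs + 1e-9)) + 1L
    i0 <- max(1L, i0); i1 <- min(length(bp), i1)
    if (i1 < i0) next
    seg <- bp[i0:i1]
    if (any(!is.finite(seg))) next
    tt <- t_samp[i0:i1]
    # extrema over samples of the half-open cycle [t_k, t_{k+1}) only;
    # interpolated boundary values would blend in the neighbouring cycles
    open_set <- tt < hi - 1e-9
    if (!any(open_set)) next
    sbp[k] <- max(seg[open_set])
    dbp[k] <- min(seg[open_set])
    # MAP integrates the entire cycle, with exact boundary values by
    # linear interpolation
    v0 <- approx(t_samp, bp, xout = lo, rule = 2L)$y
    v1 <- approx(t_samp, bp, xout = hi, rule = 2L)$y
    tt_full <- c(lo, tt, hi)
    vv_full <- c(v0, seg, v1)
    dup <- duplicated(tt_full)
    mp[k] <- trapz(tt_full[!dup], vv_full[!dup]) / (hi - lo)
    valid[k] <- TRUE
  }
  tibble(t_s = t_beats[seq_len(n_cyc)],
         sbp_mmhg = sbp, dbp_mmhg = dbp, map_mmhg = mp, valid = valid)
}

#' Detect breaths and summarize ventilation from respiratory flow
#'
#' Breaths are delimited by negative-to-positive zero crossings of the
#' low-pass-filtered flow (4th-order Butterworth, 1 Hz cutoff, zero-phase).
#' Tidal volume is the integral of inspiratory (positive) flow per breath;
#' respiratory frequency is breaths per minute over the analyzed span; and
#' minute ventilation is `Rf x mean VT`.
#'
#' @param flow Numeric respiratory flow samples (L/s, inspiration positive),
#'   or a `waveform_record` with a `flow` channel.
#' @param fs Sampling rate in Hz. Taken from the record if omitted.
#' @return A list with `rf_breaths_min`, `vt_mean_l`, `ve_l_min`,
#'   `breath_times_s` (breath onset times) and `vt_l` (per-breath volumes).
#' @export
detect_breaths <- function(flow, fs = NULL) {
  x <- channel_vector(flow, "flow", fs)
  fs <- x$fs
  flow <- x$v
  n <- length(flow)
  if (n / fs < 30) {
    stop_barosens("flow recording must be at least 30 s long",
                  "insufficient_data_error")
  }
  lp <- signal::butter(4, 1 / (fs / 2), type = "low")
  f <- filtfilt_padded(lp, flow, round(2 * fs))
  if (sd(f) < 1e-12) {
    stop_barosens("flow signal is flat; no breaths detectable",
                  "signal_quality_error")
  }
  cross <- which(f[-n] < 0 & f[-1L] >= 0) + 1L
  if (length(cross) < 2L) {
    stop_barosens("no negative-to-positive zero crossings found in flow",
                  "signal_quality_error")
  }
  t_samp <- x$t0 + (seq_len(n) - 1L) / fs
  n_breaths <- length(cross) - 1L
  vt <- vapply(seq_len(n_breaths), function(b) {
    idx <- cross[b]:(cross[b + 1L] - 1L)
    pos <- pmax(f[idx], 0)
    trapz(t_samp[idx], pos)
  }, numeric(1))
  span_min <- (t_samp[cross[length(cross)]] - t_samp[cross[1L]]) / 60
  rf <- n_breaths / span_min
  vt_mean <- mean(vt)
  list(rf_breaths_min = rf,
       vt_mean_l = vt_mean,
       ve_l_min = rf * vt_mean,
       breath_times_s = t_samp[cross[seq_len(n_breaths)]],
       vt_l = vt)
}
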