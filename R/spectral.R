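#' Frequency bands of cardiovascular variability
#'
#' The conventional very-low (<0.04 Hz), low (0.04-0.15 Hz) and high
#' (0.15-0.40 Hz) frequency ranges. Band membership is half-open
#' `[lo, hi)` except HF, which is closed at 0.40 Hz, and the DC bin is
#' excluded from VLF — so a bin at exactly 0.04 Hz belongs to exactly one
#' band (LF).
#'
#' @param vlf,lf,hf Length-2 numeric band edges in Hz.
#' @return A `band_scheme` tibble with columns `band`, `lo_hz`, `hi_hz`,
#'   `hi_closed`.
#' @export
band_scheme <- function(vlf = c(0, 0.04), lf = c(0.04, 0.15),
                        hf = c(0.15, 0.40)) {
  b <- tibble(
    band = factor(c("vlf", "lf", "hf"), levels = c("vlf", "lf", "hf")),
    lo_hz = c(vlf[1], lf[1], hf[1]),
    hi_hz = c(vlf[2], lf[2], hf[2]),
    hi_closed = c(FALSE, FALSE, TRUE)
  )
  if (any(b$hi_hz <= b$lo_hz) || any(diff(b$lo_hz) < 0) ||
      any(b$hi_hz[-3] > b$lo_hz[-1] + 1e-12)) {
    stop_barosens("bands must be ordered and non-overlapping", "config_error")
  }
  structure(b, class = c("band_scheme", class(tibble())))
}

band_member <- function(freqs, lo, hi, hi_closed) {
  inside <- freqs >= lo & (if (hi_closed) freqs <= hi + 1e-12 else freqs < hi)
  inside & freqs > 1e-12  # DC always excluded
}

hann_window <- function(L) {
  # periodic Hann taper
  0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
}

detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  tc <- t - mean(t)
  beta <- sum(tc * x) / sum(tc^2)
  x - mean(x) - beta * tc
}

#' Welch auto- and cross-spectra of SBP and RR
#'
#' Estimates one-sided auto- and cross-spectral densities by the Welch
#' method: the record is subdivided into `n_segments` segments overlapping
#' by `overlap`, each segment is linearly detrended, tapered with a
#' (periodic) Hanning window, Fourier transformed, and the modified
#' periodograms are averaged. Segment length is `L = floor(2N/(K+1))` for
#' `K` segments at 50% overlap — the unique choice that covers the full
#' record. Densities are normalized by the window power (`sum(w^2)`) so
#' that the integral of an autospectrum recovers the variance of the
#' detrended, window-weighted signal.
#'
#' With `x` the systolic pressure track and `y` the RR track, the
#' cross-spectrum is `mean(Conj(X) * Y)`, so a negative phase means RR
#' changes lag SBP changes.
#'
#' @param x,y `eq_series` (from [interpolate_resample()]) or numeric
#'   vectors of equal length sharing sampling rate `fs`.
#' @param n_segments Number of Welch segments (default 5).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param window Taper name; only `"hanning"` is implemented.
#' @param detrend Per-segment detrend; `"linear"` (default), `"mean"` or
#'   `"none"`.
#' @param fs Sampling rate in Hz; taken from `x` when it is an `eq_series`.
#' @return A `spectral_estimate`: tibble with `freq_hz`, `sxx` (mmHg^2/Hz),
#'   `syy` (ms^2/Hz) and complex `sxy` (ms.mmHg/Hz), with attributes
#'   `fs`, `n_segments`, `segment_len_s`, `window`, `detrend`.
#' @export
welch_cross_spectra <- function(x, y = x, n_segments = 5L, overlap = 0.5,
                                window = "hanning", detrend = "linear",
                                fs = NULL) {
  fs <- fs %||% attr(x, "fs", exact = TRUE)
  if (is.null(fs)) stop_barosens("`fs` missing", "config_error")
  xv <- if (is.data.frame(x)) x$value else as.numeric(x)
  yv <- if (is.data.frame(y)) y$value else as.numeric(y)
  if (length(xv) != length(yv)) {
    stop_barosens("x and y must have equal length", "config_error")
  }
  if (!identical(window, "hanning")) {
    stop_barosens("only the hanning window is implemented", "config_error")
  }
  if (!detrend %in% c("linear", "mean", "none")) {
    stop_barosens("detrend must be 'linear', 'mean' or 'none'", "config_error")
  }
  N <- length(xv)
  K <- as.integer(n_segments)
  if (abs(overlap - 0.5) < 1e-12) {
    L <- floor(2 * N / (K + 1))
  } else {
    # general overlap: L such that K hops of (1-overlap)L cover N
    L <- floor(N / (1 + (K - 1) * (1 - overlap)))
  }
  if (L < 32L) {
    stop_barosens(paste0("segment length ", L, " < 32 samples; record too ",
                         "short for ", K, " segments"),
                  "insufficient_data_error")
  }
  hop <- max(1L, floor(L * (1 - overlap)))
  starts <- (seq_len(K) - 1L) * hop + 1L
  w <- hann_window(L)
  u <- sum(w^2)
  nf <- L %/% 2L + 1L
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  dt_fun <- switch(detrend,
                   linear = detrend_linear,
                   mean = function(z) z - mean(z),
                   none = identity)
  for (s in starts) {
    xs <- dt_fun(xv[s:(s + L - 1L)]) * w
    ys <- dt_fun(yv[s:(s + L - 1L)]) * w
    X <- fft(xs)[seq_len(nf)]
    Y <- fft(ys)[seq_len(nf)]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + Conj(X) * Y
  }
  scale <- 1 / (K * fs * u)
  # one-sided: double everything except DC (and Nyquist when L is even)
  fold <- rep(2, nf)
  fold[1L] <- 1
  if (L %% 2L == 0L) fold[nf] <- 1
  structure(
    tibble(freq_hz = (seq_len(nf) - 1L) * fs / L,
           sxx = sxx * scale * fold,
           syy = syy * scale * fold,
           sxy = sxy * scale * fold),
    class = c("spectral_estimate", class(tibble())),
    fs = fs, n_segments = K, segment_len_s = L / fs,
    window = window, detrend = detrend
  )
}

#' Transfer function between SBP and RR spectra
#'
#' Computes per-frequency gain `|Sxy|/Sxx` (ms/mmHg), phase `arg(Sxy)`
#' wrapped to `(-pi, pi]` (negative phase: RR lags SBP), and
#' magnitude-squared coherence `|Sxy|^2/(Sxx Syy)`. Frequencies where the
#' input autospectrum vanishes yield missing values, never infinities.
#'
#' @param s A `spectral_estimate` from [welch_cross_spectra()] with `x` the
#'   SBP series and `y` the RR series.
#' @param bands A [band_scheme()] used for the band summaries.
#' @param coherence_min Optional coherence gate applied to the band
#'   summaries (default none).
#' @return A `tfa_result` list with elements `spectra` (per-frequency
#'   tibble), `bands` (band-summary tibble), `cbrs_lf_gain_ms_per_mmhg`,
#'   and `settings`. Use [tidy()], [glance()] and [autoplot()] on it.
#' @export
transfer_function <- function(s, bands = band_scheme(), coherence_min = NULL) {
  if (!inherits(s, "spectral_estimate")) {
    stop_barosens("`s` must come from welch_cross_spectra()", "config_error")
  }
  eps <- max(s$sxx, 0) * 1e-14
  ok <- s$sxx > eps & is.finite(s$sxx)
  gain <- ifelse(ok, Mod(s$sxy) / s$sxx, NA_real_)
  phase <- ifelse(ok, Arg(s$sxy), NA_real_)
  denom <- s$sxx * s$syy
  coh <- ifelse(ok & denom > 0, Mod(s$sxy)^2 / denom, NA_real_)
  spectra <- tibble(freq_hz = s$freq_hz,
                    sxx_mmhg2_hz = s$sxx,
                    syy_ms2_hz = s$syy,
                    gain_ms_per_mmhg = gain,
                    phase_rad = phase,
                    coherence = coh)
  bs <- band_summary_impl(spectra, s, bands, coherence_min)
  lf <- bs[bs$band == "lf", ]
  structure(list(
    spectra = spectra,
    bands = bs,
    cbrs_lf_gain_ms_per_mmhg = lf$gain_ms_per_mmhg[1L],
    settings = list(fs = attr(s, "fs", exact = TRUE),
                    n_segments = attr(s, "n_segments", exact = TRUE),
                    segment_len_s = attr(s, "segment_len_s", exact = TRUE),
                    resolution_hz = 1 / attr(s, "segment_len_s", exact = TRUE),
                    window = attr(s, "window", exact = TRUE),
                    detrend = attr(s, "detrend", exact = TRUE),
                    coherence_min = coherence_min)
  ), class = "tfa_result")
}

band_summary_impl <- function(spectra, s, bands, coherence_min) {
  purrr::pmap_dfr(bands, function(band, lo_hz, hi_hz, hi_closed) {
    m <- band_member(spectra$freq_hz, lo_hz, hi_hz, hi_closed)
    sub <- spectra[m & !is.na(spectra$gain_ms_per_mmhg), ]
    sub_all <- spectra[m, ]
    if (!is.null(coherence_min)) {
      sub <- sub[!is.na(sub$coherence) & sub$coherence >= coherence_min, ]
    }
    tibble(
      band = band,
      lo_hz = lo_hz, hi_hz = hi_hz,
      n_bins = nrow(sub),
      gain_ms_per_mmhg = mean_or_na(sub$gain_ms_per_mmhg),
      phase_rad = mean_or_na(sub$phase_rad),
      coherence = mean_or_na(sub$coherence),
      sbp_power_mmhg2 = band_power(sub_all$freq_hz, sub_all$sxx_mmhg2_hz),
      rr_power_ms2 = band_power(sub_all$freq_hz, sub_all$syy_ms2_hz)
    )
  })
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

band_power <- function(f, p, df = NA_real_) {
  keep <- is.finite(p)
  if (sum(keep) == 0L) return(NA_real_)
  if (sum(keep) == 1L) {
    # a single-bin band cannot support the trapezoid; fall back to the
    # rectangle approximation when the bin width is known
    return(if (is.finite(df)) p[keep] * df else NA_real_)
  }
  trapz(f[keep], p[keep])
}

#' Band summaries of a transfer-function result
#'
#' Unweighted means of per-bin gain, phase and coherence over the bins whose
#' center frequency falls in each band, plus trapezoid-integrated band
#' powers of both autospectra. The LF mean gain is the cBRS index.
#'
#' @param tf A `tfa_result` or `spectral_estimate`.
#' @param bands A [band_scheme()].
#' @param coherence_min Optional minimum coherence a bin must reach to
#'   contribute to the gain/phase/coherence means; `n_bins` reports how many
#'   bins contributed. Default: no gate.
#' @return The band-summary tibble (one row per band).
#' @export
band_summary <- function(tf, bands = band_scheme(), coherence_min = NULL) {
  if (inherits(tf, "spectral_estimate")) {
    tf <- transfer_function(tf, bands = bands, coherence_min = coherence_min)
    return(tf$bands)
  }
  if (!inherits(tf, "tfa_result")) {
    stop_barosens("`tf` must be a tfa_result or spectral_estimate",
                  "config_error")
  }
  band_summary_impl(tf$spectra, NULL, bands, coherence_min)
}

#' @export
print.tfa_result <- function(x, ...) {
  cat("<transfer-function analysis>\n")
  cat(sprintf("  cBRS (LF gain): %s ms/mmHg\n",
              format_maybe_na(x$cbrs_lf_gain_ms_per_mmhg)))
  cat(sprintf("  segments: %d x %.0f s, resolution %.3g Hz\n",
              x$settings$n_segments, x$settings$segment_len_s,
              x$settings$resolution_hz))
  print(x$bands)
  invisible(x)
}

format_maybe_na <- function(x) {
  if (is.na(x)) "NA" else sprintf("%.2f", x)
}

#' @rdname transfer_function
#' @param x A `tfa_result`.
#' @param ... Unused.
#' @method tidy tfa_result
#' @export
tidy.tfa_result <- function(x, ...) x$spectra

#' @rdname transfer_function
#' @method glance tfa_result
#' @export
glance.tfa_result <- function(x, ...) {
  lf <- x$bands[x$bands$band == "lf", ]
  tibble(
    cbrs_lf_gain_ms_per_mmhg = x$cbrs_lf_gain_ms_per_mmhg,
    lf_phase_rad = lf$phase_rad[1L],
    lf_coherence = lf$coherence[1L],
    n_segments = x$settings$n_segments,
    segment_len_s = x$settings$segment_len_s,
    resolution_hz = x$settings$resolution_hz
  )
}
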