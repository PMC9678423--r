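#' Time-domain heart-rate variability
#'
#' Computed on the raw, unevenly sampled beat series (never on the
#' resampled track): RMSSD is the square root of the mean squared
#' successive RR difference, and pNN50 the percentage of successive RR
#' pairs differing by strictly more than 50 ms. Successive-difference
#' pairs that span a flagged (invalid) beat are excluded.
#'
#' @param series A [beat_series], or a numeric RR vector in ms (all taken
#'   valid).
#' @return A one-row tibble with `mean_rr_ms`, `hr_beats_min`, `rmssd_ms`,
#'   `pnn50_pct`, `n_beats`, `n_pairs`.
#' @export
hrv_time_domain <- function(series) {
  if (is.numeric(series)) {
    rr <- series
    valid <- rep(TRUE, length(rr))
  } else {
    rr <- series$rr_ms
    valid <- series$valid
  }
  rr_valid <- rr[valid]
  if (length(rr_valid) < 3L) {
    stop_barosens("need at least 3 valid RR intervals",
                  "insufficient_data_error")
  }
  pair_ok <- valid[-length(valid)] & valid[-1L]
  d <- (rr[-1L] - rr[-length(rr)])[pair_ok]
  if (!length(d)) {
    stop_barosens("no successive valid RR pairs", "insufficient_data_error")
  }
  mean_rr <- mean(rr_valid)
  tibble(
    mean_rr_ms = mean_rr,
    hr_beats_min = 60000 / mean_rr,
    rmssd_ms = sqrt(mean(d^2)),
    pnn50_pct = 100 * mean(abs(d) > 50),
    n_beats = length(rr_valid),
    n_pairs = length(d)
  )
}

#' Frequency-domain heart-rate variability
#'
#' Band powers of the RR autospectrum integrated (trapezoid over bins) in
#' the VLF, LF and HF ranges, from the same Welch machinery as the
#' transfer-function analysis. Total power is defined as VLF + LF + HF
#' (i.e. up to 0.40 Hz) so the normalized units
#' `lf_nu = 100 lf / (total - vlf)` and `hf_nu = 100 hf / (total - vlf)`
#' sum to exactly 100; set `total_to_nyquist = TRUE` to instead integrate
#' the full spectrum into `total_power_ms2`.
#'
#' @param rr_eq An `eq_series` of RR (from [interpolate_resample()]), or a
#'   `spectral_estimate` already computed with RR as `y`.
#' @param bands A [band_scheme()].
#' @param n_segments,overlap Welch settings (defaults 5 and 0.5), used when
#'   `rr_eq` is a series.
#' @param total_to_nyquist If `TRUE`, `total_power_ms2` integrates up to the
#'   Nyquist frequency (normalized units are unaffected).
#' @return A one-row tibble with `vlf_power_ms2`, `lf_power_ms2`,
#'   `hf_power_ms2`, `total_power_ms2`, `lf_nu_pct`, `hf_nu_pct`, `lf_hf_au`.
#' @export
hrv_frequency_domain <- function(rr_eq, bands = band_scheme(),
                                 n_segments = 5L, overlap = 0.5,
                                 total_to_nyquist = FALSE) {
  s <- if (inherits(rr_eq, "spectral_estimate")) {
    rr_eq
  } else {
    welch_cross_spectra(rr_eq, rr_eq, n_segments = n_segments,
                        overlap = overlap)
  }
  df <- if (nrow(s) > 1L) s$freq_hz[2L] - s$freq_hz[1L] else NA_real_
  pw <- vapply(seq_len(nrow(bands)), function(i) {
    m <- band_member(s$freq_hz, bands$lo_hz[i], bands$hi_hz[i],
                     bands$hi_closed[i])
    band_power(s$freq_hz[m], s$syy[m], df = df)
  }, numeric(1))
  names(pw) <- as.character(bands$band)
  vlf <- pw[["vlf"]]; lf <- pw[["lf"]]; hf <- pw[["hf"]]
  total_bands <- vlf + lf + hf
  total <- if (total_to_nyquist) {
    band_power(s$freq_hz[s$freq_hz > 1e-12], s$syy[s$freq_hz > 1e-12],
               df = df)
  } else {
    total_bands
  }
  denom <- total_bands - vlf
  tibble(
    vlf_power_ms2 = vlf,
    lf_power_ms2 = lf,
    hf_power_ms2 = hf,
    total_power_ms2 = total,
    lf_nu_pct = if (is.finite(denom) && denom > 0) 100 * lf / denom
                else NA_real_,
    hf_nu_pct = if (is.finite(denom) && denom > 0) 100 * hf / denom
                else NA_real_,
    lf_hf_au = if (is.finite(hf) && hf > 0 && is.finite(lf)) lf / hf
               else NA_real_
  )
}
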