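#' Analyze one recording session end to end
#'
#' Orchestrates the full pipeline: beat detection (when given raw
#' waveforms), RR/SBP alignment, artifact flagging, suitability assessment,
#' spline resampling to an equidistant grid, Welch cross-spectral
#' transfer-function analysis (cBRS = LF gain), and time- and
#' frequency-domain HRV. The result is a pure function of the input and the
#' settings, all of which are recorded in the output for provenance.
#'
#' Sessions whose ectopic/artifact fraction exceeds
#' `max_ectopic_fraction` are refused (a `barosens_suitability_error`
#' carrying the fraction) unless `force = TRUE`, in which case the result
#' carries only the flag and reason — no cBRS or HRV values are reported
#' for an unsuitable session.
#'
#' @param input A `waveform_record` (channels `ecg`, `bp`, optionally
#'   `flow`) or a [beat_series].
#' @param meta Named list of session metadata (`participant`, `day`,
#'   `trial`, optionally `spo2_pct`, which is passthrough metadata, not
#'   computed).
#' @param resample_hz Equidistant resampling rate (default 4 Hz).
#' @param n_segments,overlap Welch settings (defaults 5 segments, 50%).
#' @param bands A [band_scheme()].
#' @param coherence_min Optional coherence gate for band summaries.
#' @param lag_beats RR/SBP pairing lag in beats (default 0).
#' @param rel_threshold,window Artifact-flagging settings
#'   (see [flag_artifacts()]).
#' @param max_ectopic_fraction Suitability ceiling (default 0.05).
#' @param force Analyze even an unsuitable session's hemodynamics
#'   (cBRS/HRV stay missing).
#' @return A `session_result` list with elements `meta`, `ventilation`,
#'   `hemodynamics`, `tf`, `hrv`, `suitability`, `settings`. Use [tidy()]
#'   for the flat one-row form and [write_results()] to serialize.
#' @export
analyze_session <- function(input, meta = list(),
                            resample_hz = 4, n_segments = 5L, overlap = 0.5,
                            bands = band_scheme(), coherence_min = NULL,
                            lag_beats = 0L, rel_threshold = 0.30,
                            window = 11L, max_ectopic_fraction = 0.05,
                            force = FALSE) {
  ventilation <- NULL
  if (inherits(input, "waveform_record")) {
    fs <- attr(input, "fs", exact = TRUE)
    beats <- detect_r_peaks(input, fs)
    pressures <- extract_pressure_beats(input, fs, beats)
    series <- build_beat_series(beats, pressures, lag_beats = lag_beats)
    if ("flow" %in% names(input)) {
      ventilation <- detect_breaths(input, fs)
    }
  } else if (inherits(input, "beat_series")) {
    series <- input
    if (lag_beats != 0L) {
      series <- new_beat_series(tibble(
        t_s = series$t_s, rr_ms = series$rr_ms,
        sbp_mmhg = shift_lag(series$sbp_mmhg, lag_beats),
        dbp_mmhg = shift_lag(series$dbp_mmhg, lag_beats),
        map_mmhg = shift_lag(series$map_mmhg, lag_beats),
        valid = series$valid & is.finite(shift_lag(series$sbp_mmhg, lag_beats))
      ))
    }
  } else {
    stop_barosens("`input` must be a waveform_record or beat_series",
                  "config_error")
  }

  series <- flag_artifacts(series, rel_threshold = rel_threshold,
                           window = window)
  suit <- assess_suitability(series, max_ectopic_fraction)
  if (!suit$suitable && !force) {
    rlang::abort(
      paste0("session unsuitable: ", suit$reason),
      class = c("barosens_suitability_error", "barosens_error"),
      ectopic_fraction = suit$ectopic_fraction
    )
  }

  hemo <- with(series[series$valid, ], tibble(
    sbp_mmhg = mean(sbp_mmhg),
    dbp_mmhg = mean(dbp_mmhg),
    map_mmhg = mean(map_mmhg),
    hr_beats_min = 60000 / mean(rr_ms),
    rr_s = mean(rr_ms) / 1000
  ))

  tf <- NULL
  hrv <- NULL
  if (suit$suitable) {
    rr_eq <- interpolate_resample(series, "rr", fs = resample_hz)
    sbp_eq <- interpolate_resample(series, "sbp", fs = resample_hz)
    spec <- welch_cross_spectra(sbp_eq, rr_eq, n_segments = n_segments,
                                overlap = overlap)
    tf <- transfer_function(spec, bands = bands, coherence_min = coherence_min)
    td <- hrv_time_domain(series)
    fd <- hrv_frequency_domain(spec, bands = bands)
    hrv <- dplyr::bind_cols(td, fd)
  }

  structure(list(
    meta = meta,
    ventilation = ventilation,
    hemodynamics = hemo,
    tf = tf,
    hrv = hrv,
    suitability = suit,
    settings = list(resample_hz = resample_hz, n_segments = n_segments,
                    overlap = overlap, lag_beats = lag_beats,
                    rel_threshold = rel_threshold, window = window,
                    max_ectopic_fraction = max_ectopic_fraction,
                    bands = as.data.frame(bands),
                    coherence_min = coherence_min)
  ), class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat("<session_result>\n")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  cat(sprintf("  suitable: %s (ectopic fraction %.1f%%)\n",
              x$suitability$suitable, 100 * x$suitability$ectopic_fraction))
  if (!is.null(x$tf)) {
    cat(sprintf("  cBRS (LF gain): %s ms/mmHg\n",
                format_maybe_na(x$tf$cbrs_lf_gain_ms_per_mmhg)))
  }
  if (!is.null(x$hrv)) {
    cat(sprintf("  HR %.1f beats/min, RMSSD %.1f ms, pNN50 %.1f%%\n",
                x$hrv$hr_beats_min, x$hrv$rmssd_ms, x$hrv$pnn50_pct))
  }
  invisible(x)
}

#' Flatten a session result to one row
#'
#' @param x A `session_result`.
#' @param ... Unused.
#' @return A one-row tibble in [session_result_schema()] column order;
#'   missing stages yield `NA` columns.
#' @method tidy session_result
#' @export
tidy.session_result <- function(x, ...) {
  g <- if (is.null(x$tf)) NULL else glance(x$tf)
  h <- x$hrv
  v <- x$ventilation
  row <- tibble(
    participant = as.character(x$meta$participant %||% NA_character_),
    day = as.character(x$meta$day %||% NA_character_),
    trial = as.character(x$meta$trial %||% NA_character_),
    suitable = x$suitability$suitable,
    ectopic_fraction = x$suitability$ectopic_fraction,
    spo2_pct = as.numeric(x$meta$spo2_pct %||% NA_real_),
    ve_l_min = v$ve_l_min %||% NA_real_,
    rf_breaths_min = v$rf_breaths_min %||% NA_real_,
    vt_l = v$vt_mean_l %||% NA_real_,
    sbp_mmhg = x$hemodynamics$sbp_mmhg,
    dbp_mmhg = x$hemodynamics$dbp_mmhg,
    map_mmhg = x$hemodynamics$map_mmhg,
    hr_beats_min = x$hemodynamics$hr_beats_min,
    rr_s = x$hemodynamics$rr_s,
    cbrs_lf_gain_ms_per_mmhg = if (is.null(g)) NA_real_ else
      g$cbrs_lf_gain_ms_per_mmhg,
    cbrs_lf_phase_rad = if (is.null(g)) NA_real_ else g$lf_phase_rad,
    cbrs_lf_coherence = if (is.null(g)) NA_real_ else g$lf_coherence,
    vlf_power_ms2 = h$vlf_power_ms2 %||% NA_real_,
    lf_power_ms2 = h$lf_power_ms2 %||% NA_real_,
    hf_power_ms2 = h$hf_power_ms2 %||% NA_real_,
    lf_power_pct = h$lf_nu_pct %||% NA_real_,
    hf_power_pct = h$hf_nu_pct %||% NA_real_,
    lf_hf_au = h$lf_hf_au %||% NA_real_,
    pnn50_pct = h$pnn50_pct %||% NA_real_,
    rmssd_ms = h$rmssd_ms %||% NA_real_
  )
  row[, session_result_schema()]
}

#' Required inspired oxygen fraction to hit a target PIO2
#'
#' In a hypobaric chamber the inspired oxygen partial pressure is
#' `PIO2 = FO2 x (PB - 47 mmHg)`, with 47 mmHg the water vapor pressure of
#' saturated air at 37 degrees C. Inverting gives the oxygen fraction a
#' hyperoxic mixture needs in order to restore a target PIO2 at a reduced
#' barometric pressure: `FO2 = PIO2_target / (PB - PH2O)`. At
#' `PB = 493.5` mmHg (about 3500 m) and a low-altitude target
#' `PIO2 = 145` mmHg this gives 0.3247, i.e. a 32% mixture.
#'
#' @param pb Barometric pressure, mmHg.
#' @param pio2_target Target inspired O2 partial pressure, mmHg
#'   (default 145).
#' @param ph2o Water vapor pressure, mmHg (default 47).
#' @return The required O2 fraction in (0, 1).
#' @export
required_o2_fraction <- function(pb, pio2_target = 145, ph2o = 47) {
  if (!is.numeric(pb) || pb <= ph2o) {
    stop_barosens("barometric pressure must exceed the water vapor pressure",
                  "domain_error")
  }
  frac <- pio2_target / (pb - ph2o)
  if (frac <= 0 || frac >= 1) {
    stop_barosens("target PIO2 not reachable at this barometric pressure",
                  "domain_error")
  }
  frac
}

#' @rdname required_o2_fraction
#' @return `fo2_percent()`: the fraction rounded to the nearest integer
#'   percent, as a string like `"32%"`.
#' @export
fo2_percent <- function(pb, pio2_target = 145, ph2o = 47) {
  sprintf("%d%%", round(100 * required_o2_fraction(pb, pio2_target, ph2o)))
}

#' Descriptive group summaries of session results
#'
#' Per-variable, per-group descriptive statistics in the style of a
#' physiology results table: mean and sample SD (n-1) for variables flagged
#' normal, median and interquartile range (quartiles by linear interpolation
#' between order statistics, `type = 7`) otherwise. Inferential statistics
#' are deliberately out of scope; feed the returned tibble to standard
#' routines for that.
#'
#' @param data A data frame of per-session rows (e.g. stacked
#'   `tidy(session_result)` rows).
#' @param variables Character vector of numeric columns to summarize.
#' @param by Character vector of grouping columns (e.g. `c("day", "trial")`).
#' @param normal Named logical vector: `TRUE` -> mean +/- SD path,
#'   `FALSE` -> median \[IQR\] path. Unnamed variables default to `TRUE`.
#' @param quartile_type Quantile algorithm (default 7, linear
#'   interpolation).
#' @return A tibble with one row per group x variable: `n` (non-missing),
#'   `mean`, `sd`, `median`, `q1`, `q3` and a formatted `display` string
#'   following the variable's normality flag.
#' @export
group_summary <- function(data, variables, by = character(),
                          normal = NULL, quartile_type = 7) {
  missing_vars <- setdiff(c(variables, by), names(data))
  if (length(missing_vars)) {
    stop_barosens(paste0("data lacks column(s): ",
                         paste(missing_vars, collapse = ", ")),
                  "config_error")
  }
  if (length(by)) {
    groups <- dplyr::distinct(data[, by, drop = FALSE])
    empty <- purrr::map_lgl(seq_len(nrow(groups)), function(i) {
      sel <- rep(TRUE, nrow(data))
      for (b in by) sel <- sel & data[[b]] == groups[[b]][i]
      sum(sel) < 2L
    })
    if (any(empty)) {
      bad <- groups[empty, , drop = FALSE]
      stop_barosens(paste0("group with fewer than 2 sessions: ",
                           paste(apply(bad, 1, paste, collapse = "/"),
                                 collapse = ", ")),
                    "insufficient_data_error")
    }
  } else if (nrow(data) < 2L) {
    stop_barosens("need at least 2 sessions", "insufficient_data_error")
  }
  long <- tidyr::pivot_longer(data[, c(by, variables)],
                              cols = dplyr::all_of(variables),
                              names_to = "variable", values_to = "value")
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "variable")))) |>
    dplyr::summarise(
      n = sum(is.finite(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      median = median(.data$value, na.rm = TRUE),
      q1 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE,
                    type = quartile_type),
      q3 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE,
                    type = quartile_type),
      .groups = "drop"
    )
  norm_for <- function(v) {
    if (is.null(normal) || is.null(names(normal))) TRUE
    else if (v %in% names(normal)) isTRUE(normal[[v]]) else TRUE
  }
  out$normal <- purrr::map_lgl(out$variable, norm_for)
  out$display <- ifelse(
    out$normal,
    sprintf("%.3g ± %.3g", out$mean, out$sd),
    sprintf("%.3g [%.3g–%.3g]", out$median, out$q1, out$q3)
  )
  out
}
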