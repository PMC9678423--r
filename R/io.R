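#' Read a delimited multi-channel waveform export
#'
#' Chart-recorder style acquisition systems commonly export raw signals
#' (ECG, continuous finger arterial pressure, respiratory flow) as one
#' delimited text file with a header row and one column per channel, sampled
#' uniformly. The sampling rate is never inferred from the file; it must be
#' supplied.
#'
#' @param path Path to a tab- or comma-delimited text file with a header row.
#' @param fs Sampling rate in Hz (> 0; beat detection wants >= 250 Hz).
#' @param column_map Named character vector mapping channel name to file
#'   column, e.g. `c(ecg = "ECG", bp = "Pressure", flow = "Flow")`.
#'   Channel units are taken to be mV (ecg), mmHg (bp) and L/s (flow).
#' @param t0 Recording start offset in seconds (default 0).
#' @param meta Free-form named list of session metadata (participant id,
#'   day, trial, ...).
#'
#' @return A `waveform_record`: a tibble with column `t_s` (time in s) and
#'   one column per requested channel, plus attributes `fs`, `t0` and `meta`.
#'
#' @details Non-finite samples in any mapped column are a data error (the
#'   offending row is named); readers never silently drop rows.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("ecg\tbp", "0.1\t80", "0.2\t81", "0.05\t83"), tf)
#' w <- read_waveform_delimited(tf, fs = 100, column_map = c(ecg = "ecg", bp = "bp"))
#' attr(w, "fs")
#' @export
read_waveform_delimited <- function(path, fs, column_map, t0 = 0,
                                    meta = list()) {
  if (!file.exists(path)) {
    stop_barosens(paste0("waveform file not found: ", path), "io_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_barosens("`fs` must be a single positive number (Hz)", "config_error")
  }
  if (is.null(names(column_map)) || any(!nzchar(names(column_map)))) {
    stop_barosens("`column_map` must be a named vector: channel = column",
                  "config_error")
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  # base strtod parses doubles with correct rounding, keeping round trips
  # bit-exact
  raw <- utils::read.delim(path, sep = delim, check.names = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols)) {
    stop_barosens(paste0("waveform file lacks column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "format_error")
  }
  out <- tibble(t_s = t0 + (seq_len(nrow(raw)) - 1L) / fs)
  for (ch in names(column_map)) {
    v <- as.numeric(raw[[column_map[[ch]]]])
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop_barosens(paste0("non-finite sample in channel '", ch,
                           "' at row ", bad[1L]), "data_error")
    }
    out[[ch]] <- v
  }
  if (nrow(out) < 2L) {
    stop_barosens("waveform must contain at least 2 samples", "data_error")
  }
  new_waveform_record(out, fs = fs, t0 = t0, meta = meta)
}

new_waveform_record <- function(df, fs, t0 = 0, meta = list()) {
  structure(df,
            class = c("waveform_record", class(tibble())),
            fs = fs, t0 = t0, meta = meta)
}

#' Write a waveform record back to delimited text
#'
#' Values are written with shortest round-trip formatting, so
#' `read_waveform_delimited(write_waveform_delimited(w))` reproduces the
#' samples bit-exactly.
#'
#' @param record A `waveform_record`.
#' @param path Output path.
#' @param delim Field delimiter, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_waveform_delimited <- function(record, path, delim = "\t") {
  chans <- setdiff(names(record), "t_s")
  df <- as_tibble(record)[, chans, drop = FALSE]
  # 17 significant digits guarantee a bit-exact double round trip
  cols <- lapply(df, function(col) sprintf("%.17g", col))
  lines <- c(paste(chans, collapse = delim),
             do.call(paste, c(cols, sep = delim)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a beat table CSV
#'
#' The beat-table dialect is a comma-delimited, point-decimal file with a
#' header and columns `t_s, rr_ms, sbp_mmhg, dbp_mmhg, map_mmhg` and an
#' optional logical `valid`. Each row is one cardiac cycle: `t_s` is the time
#' of the beat opening the cycle, `rr_ms` the interval it opens, and the
#' pressures belong to that same cycle.
#'
#' Rows are never dropped: physiologically impossible rows (`rr_ms <= 0`,
#' `sbp <= dbp`) and rows with missing fields are flagged invalid instead.
#' A decreasing `t_s` is a format error naming the first offending row.
#'
#' @param path Path to the CSV file.
#' @return A [beat_series] tibble.
#' @export
read_beat_table <- function(path) {
  if (!file.exists(path)) {
    stop_barosens(paste0("beat table not found: ", path), "io_error")
  }
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c("t_s", "rr_ms", "sbp_mmhg", "dbp_mmhg", "map_mmhg")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_barosens(paste0("beat table lacks column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "format_error")
  }
  t_s <- as.numeric(raw$t_s)
  if (anyNA(t_s)) {
    stop_barosens(paste0("missing beat time at row ", which(is.na(t_s))[1L]),
                  "format_error")
  }
  dec <- which(diff(t_s) <= 0)
  if (length(dec)) {
    stop_barosens(paste0("beat times must be strictly increasing; first ",
                         "violation at row ", dec[1L] + 1L), "format_error")
  }
  valid <- if ("valid" %in% names(raw)) {
    isTRUE_vec(raw$valid)
  } else {
    rep(TRUE, nrow(raw))
  }
  ok <- complete.cases(raw[, need]) &
    raw$rr_ms > 0 & raw$sbp_mmhg > raw$dbp_mmhg
  ok[is.na(ok)] <- FALSE
  new_beat_series(tibble(
    t_s = t_s,
    rr_ms = as.numeric(raw$rr_ms),
    sbp_mmhg = as.numeric(raw$sbp_mmhg),
    dbp_mmhg = as.numeric(raw$dbp_mmhg),
    map_mmhg = as.numeric(raw$map_mmhg),
    valid = valid & ok
  ))
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- tolower(as.character(x))
  x %in% c("true", "t", "1", "yes")
}

#' Write a beat series as a beat-table CSV
#'
#' @param series A [beat_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beat_table <- function(series, path) {
  readr::write_csv(as_tibble(series)[, c("t_s", "rr_ms", "sbp_mmhg",
                                         "dbp_mmhg", "map_mmhg", "valid")],
                   path, progress = FALSE)
  invisible(path)
}

#' Result schema of a per-session CSV row
#'
#' Column order follows the conventional reporting table of resting
#' cardiorespiratory studies: oxygen saturation and ventilation first, then
#' hemodynamics, then baroreflex transfer-function summaries, then HRV.
#' Every numeric key carries its unit in the name.
#'
#' @return Character vector of column names.
#' @export
session_result_schema <- function() {
  c("participant", "day", "trial",
    "suitable", "ectopic_fraction",
    "spo2_pct", "ve_l_min", "rf_breaths_min", "vt_l",
    "sbp_mmhg", "dbp_mmhg", "map_mmhg", "hr_beats_min", "rr_s",
    "cbrs_lf_gain_ms_per_mmhg", "cbrs_lf_phase_rad", "cbrs_lf_coherence",
    "vlf_power_ms2", "lf_power_ms2", "hf_power_ms2",
    "lf_power_pct", "hf_power_pct", "lf_hf_au",
    "pnn50_pct", "rmssd_ms")
}

#' Write a session result to CSV or JSON
#'
#' The CSV form is one row per session in [session_result_schema()] order.
#' The JSON form nests the same values under stable, documented keys
#' (`meta`, `suitability`, `ventilation`, `hemodynamics`, `cbrs`, `hrv`,
#' `settings`), every numeric key carrying its unit.
#'
#' @param result A `session_result` from [analyze_session()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, format = c("csv", "json")) {
  if (!inherits(result, "session_result")) {
    stop_barosens("`result` must be a session_result", "config_error")
  }
  if (length(format) == 1L && !format %in% c("csv", "json")) {
    stop_barosens(paste0("unsupported format: ", format), "format_error")
  }
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_barosens(paste0("output directory does not exist: ", dir), "io_error")
  }
  if (format == "csv") {
    row <- tidy(result)
    stopifnot(identical(names(row), session_result_schema()))
    readr::write_csv(row, path, progress = FALSE)
  } else {
    jsonlite::write_json(session_result_json(result), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

session_result_json <- function(result) {
  g <- glance(result$tf)
  hrv <- result$hrv
  list(
    meta = result$meta,
    suitability = list(
      suitable = result$suitability$suitable,
      ectopic_fraction = result$suitability$ectopic_fraction,
      reason = result$suitability$reason
    ),
    ventilation = if (is.null(result$ventilation)) NULL else list(
      rf_breaths_min = result$ventilation$rf_breaths_min,
      vt_l = result$ventilation$vt_mean_l,
      ve_l_min = result$ventilation$ve_l_min
    ),
    hemodynamics = as.list(result$hemodynamics),
    cbrs = if (is.null(g)) NULL else list(
      cbrs_lf_gain_ms_per_mmhg = g$cbrs_lf_gain_ms_per_mmhg,
      cbrs_lf_phase_rad = g$lf_phase_rad,
      cbrs_lf_coherence = g$lf_coherence
    ),
    hrv = if (is.null(hrv)) NULL else as.list(hrv),
    settings = result$settings
  )
}

#' Write per-frequency spectra to CSV
#'
#' @param tf A `tfa_result` from [transfer_function()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(tf, path) {
  df <- tidy(tf)
  df <- df[, c("freq_hz", "sxx_mmhg2_hz", "syy_ms2_hz",
               "gain_ms_per_mmhg", "phase_rad", "coherence")]
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
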