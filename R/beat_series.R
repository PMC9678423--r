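#' Beat series: the pipeline's central object
#'
#' A `beat_series` is a tibble with one row per cardiac cycle:
#' \describe{
#'   \item{t_s}{time of the beat opening the cycle, seconds from start}
#'   \item{rr_ms}{RR interval opened by that beat, ms}
#'   \item{sbp_mmhg, dbp_mmhg, map_mmhg}{systolic, diastolic and mean
#'     pressure of the same cycle}
#'   \item{valid}{per-cycle validity flag; invalid cycles are kept, never
#'     dropped, and excluded from interpolation support and HRV statistics}
#' }
#' The attribute `ectopic_fraction` (set by [flag_artifacts()]) is the
#' proportion of cycles flagged, and `t_end_s` is the time of the beat
#' closing the last cycle.
#'
#' @param df Tibble with the columns above (`valid` optional).
#' @return A `beat_series` tibble.
#' @export
new_beat_series <- function(df) {
  if (!"valid" %in% names(df)) df$valid <- rep(TRUE, nrow(df))
  need <- c("t_s", "rr_ms", "sbp_mmhg", "dbp_mmhg", "map_mmhg", "valid")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_barosens(paste0("beat series lacks column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "config_error")
  }
  df <- as_tibble(df)[, need]
  structure(df,
            class = c("beat_series", class(tibble())),
            ectopic_fraction = attr(df, "ectopic_fraction", exact = TRUE),
            t_end_s = df$t_s[nrow(df)] + df$rr_ms[nrow(df)] / 1000)
}

#' Proportion of cycles flagged as ectopic/artifact
#'
#' @param series A [beat_series] after [flag_artifacts()].
#' @return A single proportion in \[0, 1\], or `NA` if flagging has not run.
#' @export
ectopic_fraction <- function(series) {
  attr(series, "ectopic_fraction", exact = TRUE) %||% NA_real_
}

#' Build an aligned RR/SBP beat series
#'
#' Pairs each RR interval with the pressures of the cycle it spans, at zero
#' lag: `rr_k` (interval from beat k to beat k+1) is paired with `sbp_k`
#' (systole of that same cycle). This is the conventional alignment of
#' spontaneous baroreflex transfer-function analysis; use `lag_beats` to
#' study alternative pairings (positive lag pairs `rr_k` with the systole
#' `lag` beats earlier).
#'
#' @param beats R-peak annotations: output of [detect_r_peaks()], or a
#'   numeric vector of beat times in seconds.
#' @param pressures Per-cycle pressures from [extract_pressure_beats()]
#'   (one row per complete cycle, i.e. `length(beats) - 1` rows).
#' @param lag_beats Integer pairing lag in beats (default 0).
#' @param min_beats Fewest beats accepted (default 30; spectral stages want
#'   a full 5-min recording, but the alignment arithmetic itself is defined
#'   from 2 beats up, so small worked examples may lower this).
#' @return A [beat_series].
#' @export
build_beat_series <- function(beats, pressures, lag_beats = 0L,
                              min_beats = 30L) {
  t_beats <- if (is.numeric(beats)) beats else beats$t_s
  n <- length(t_beats)
  if (n < max(2L, min_beats)) {
    stop_barosens(paste0("only ", n, " beats; at least ", max(2L, min_beats),
                         " are required (ideally a 5-min recording)"),
                  "insufficient_data_error")
  }
  if (any(diff(t_beats) <= 0)) {
    stop_barosens("beat times must be strictly increasing", "data_error")
  }
  if (nrow(pressures) != n - 1L) {
    stop_barosens(paste0("pressures must have one row per complete cycle (",
                         n - 1L, "), got ", nrow(pressures)), "config_error")
  }
  rr <- diff(t_beats) * 1000
  sbp <- shift_lag(pressures$sbp_mmhg, lag_beats)
  dbp <- shift_lag(pressures$dbp_mmhg, lag_beats)
  mp <- shift_lag(pressures$map_mmhg, lag_beats)
  pvalid <- if ("valid" %in% names(pressures)) {
    shift_lag_lgl(pressures$valid, lag_beats)
  } else {
    rep(TRUE, n - 1L)
  }
  new_beat_series(tibble(
    t_s = t_beats[-n],
    rr_ms = rr,
    sbp_mmhg = sbp,
    dbp_mmhg = dbp,
    map_mmhg = mp,
    valid = pvalid & rr > 0 & is.finite(sbp)
  ))
}

shift_lag <- function(x, lag) {
  lag <- as.integer(lag)
  if (lag == 0L) return(x)
  n <- length(x)
  if (lag > 0L) c(rep(NA_real_, lag), x[seq_len(n - lag)])
  else c(x[(1L - lag):n], rep(NA_real_, -lag))
}

shift_lag_lgl <- function(x, lag) {
  out <- shift_lag(as.numeric(x), lag)
  !is.na(out) & out > 0
}

#' Flag ectopic beats and artifacts in the RR series
#'
#' A cycle is flagged when its RR interval deviates from the rolling median
#' by more than `rel_threshold` of that median. The rule targets
#' compensated ectopy (a premature beat roughly halves one RR interval)
#' while being robust to the slow oscillations of a genuine tachogram.
#' Flagged cycles are retained but marked invalid, so later stages
#' interpolate over them rather than use their values.
#'
#' @param series A [beat_series].
#' @param rel_threshold Relative deviation from the rolling median that
#'   triggers a flag (default 0.30).
#' @param window Rolling-median window in beats; odd, >= 3 (default 11).
#' @return The series with `valid` updated and the `ectopic_fraction`
#'   attribute set.
#' @export
flag_artifacts <- function(series, rel_threshold = 0.30, window = 11L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop_barosens("`window` must be odd and >= 3", "config_error")
  }
  rr <- series$rr_ms
  n <- length(rr)
  k <- min(window, if (n %% 2L == 1L) n else n - 1L)
  med <- if (k >= 3L) runmed(rr, k, endrule = "median") else rep(median(rr), n)
  flag <- abs(rr - med) > rel_threshold * med
  flag[!is.finite(flag)] <- TRUE
  out <- series
  out$valid <- series$valid & !flag
  frac <- mean(flag | !series$valid)
  attr(out, "ectopic_fraction") <- frac
  out
}

#' Decide whether a session is suitable for cBRS/HRV analysis
#'
#' Sessions with frequent ectopy cannot support spontaneous baroreflex or
#' HRV estimation; following common practice such sessions are excluded
#' rather than repaired. The default ceiling is 5% flagged cycles
#' (inclusive).
#'
#' @param series A [beat_series] after [flag_artifacts()].
#' @param max_ectopic_fraction Largest acceptable flagged proportion
#'   (default 0.05).
#' @return A list with `suitable` (logical), `ectopic_fraction`, and
#'   `reason` (`NA` when suitable).
#' @export
assess_suitability <- function(series, max_ectopic_fraction = 0.05) {
  frac <- ectopic_fraction(series)
  if (is.na(frac)) {
    stop_barosens("run flag_artifacts() before assess_suitability()",
                  "config_error")
  }
  ok <- frac <= max_ectopic_fraction
  list(
    suitable = ok,
    ectopic_fraction = frac,
    reason = if (ok) NA_character_ else
      sprintf(paste0("ectopic/artifact fraction %.1f%% exceeds the %.1f%% ",
                     "ceiling; frequent ectopy invalidates spontaneous ",
                     "baroreflex and HRV analysis"),
              100 * frac, 100 * max_ectopic_fraction)
  )
}

#' Resample a beat channel to an equidistant grid
#'
#' Fits a natural cubic spline through the valid beats of the requested
#' channel and samples it at `fs` (default 4 Hz) over the interior span
#' only — the output grid never extends beyond the first or last valid
#' beat, so no extrapolation occurs. Flagged (invalid) beats are excluded
#' from the spline support and therefore interpolated over.
#'
#' @param series A [beat_series].
#' @param channel `"rr"`, `"sbp"`, `"dbp"` or `"map"`.
#' @param fs Output sampling rate in Hz (default 4).
#' @return An `eq_series`: tibble with `t_s` and `value`, with attributes
#'   `fs` and `channel`.
#' @export
interpolate_resample <- function(series, channel = c("rr", "sbp", "dbp", "map"),
                                 fs = 4) {
  channel <- match.arg(channel)
  col <- c(rr = "rr_ms", sbp = "sbp_mmhg", dbp = "dbp_mmhg",
           map = "map_mmhg")[[channel]]
  keep <- series$valid & is.finite(series[[col]]) & is.finite(series$t_s)
  t <- series$t_s[keep]
  v <- series[[col]][keep]
  if (length(t) < 4L) {
    stop_barosens("need at least 4 valid beats to fit the spline",
                  "insufficient_data_error")
  }
  span <- t[length(t)] - t[1L]
  if (span < 2) {
    stop_barosens("valid-beat span shorter than 2 s", "insufficient_data_error")
  }
  grid <- t[1L] + seq(0L, floor(span * fs)) / fs
  f <- splinefun(t, v, method = "natural")
  new_eq_series(tibble(t_s = grid, value = f(grid)), fs = fs, channel = channel)
}

new_eq_series <- function(df, fs, channel) {
  structure(df,
            class = c("eq_series", class(tibble())),
            fs = fs, channel = channel)
}

#' @export
print.beat_series <- function(x, ...) {
  n <- nrow(x)
  frac <- ectopic_fraction(x)
  cat(sprintf("<beat_series: %d cycles over %.1f s, %s flagged>\n",
              n, attr(x, "t_end_s") - x$t_s[1L],
              if (is.na(frac)) "not yet" else sprintf("%.1f%%", 100 * frac)))
  NextMethod()
}
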