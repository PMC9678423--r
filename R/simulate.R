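#' Closed-loop cardiovascular variability simulator configuration
#'
#' Defines a beat-to-beat generative model of resting cardiovascular
#' variability with a known baroreflex gain, used to verify every pipeline
#' stage by parameter recovery. Systolic pressure carries a Mayer-wave
#' (~0.1 Hz) and a respiratory (~0.25 Hz) oscillation plus beat-to-beat
#' noise; the RR interval responds to systolic pressure `delay_beats`
#' earlier with gain `gain_true` (ms/mmHg), plus a direct respiratory
#' modulation (respiratory sinus arrhythmia) and noise. Each RR interval
#' sets the time of the next beat (event-driven generation).
#'
#' @param duration_s Recording length in s (default 300, a 5-min resting
#'   recording).
#' @param rr0 Baseline RR interval, ms.
#' @param sbp0 Baseline systolic pressure, mmHg.
#' @param gain_true Programmed baroreflex gain, ms/mmHg.
#' @param delay_beats Baroreflex latency in beats (integer >= 0).
#' @param a_lf,f_lf Mayer-wave SBP amplitude (mmHg) and frequency (Hz,
#'   default 0.10, inside the LF band).
#' @param a_hf,f_hf Respiratory SBP amplitude (mmHg) and frequency (Hz,
#'   default 0.25, inside the HF band).
#' @param rsa_ms Direct respiratory RR modulation amplitude, ms.
#' @param sbp_noise_sd,rr_noise_sd Beat-to-beat Gaussian noise SDs.
#' @param ectopic_rate Fraction of beats turned into ectopics (RR halved).
#' @param pulse_pressure Pulse pressure used to derive DBP/MAP, mmHg.
#' @param seed Master seed; per-channel substreams are derived from it so
#'   toggling one noise source never changes the other draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration_s = 300, rr0 = 800, sbp0 = 120,
                       gain_true = 10, delay_beats = 1L,
                       a_lf = 2.5, f_lf = 0.10,
                       a_hf = 1.5, f_hf = 0.25,
                       rsa_ms = 30, sbp_noise_sd = 1.5, rr_noise_sd = 6,
                       ectopic_rate = 0, pulse_pressure = 45, seed = 1L) {
  cfg <- list(duration_s = duration_s, rr0 = rr0, sbp0 = sbp0,
              gain_true = gain_true, delay_beats = as.integer(delay_beats),
              a_lf = a_lf, f_lf = f_lf, a_hf = a_hf, f_hf = f_hf,
              rsa_ms = rsa_ms, sbp_noise_sd = sbp_noise_sd,
              rr_noise_sd = rr_noise_sd, ectopic_rate = ectopic_rate,
              pulse_pressure = pulse_pressure, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (rr0 < 300 || rr0 > 2000) {
      stop_barosens("rr0 must lie in [300, 2000] ms", "config_error")
    }
    if (f_lf < 0.04 || f_lf >= 0.15) {
      stop_barosens("f_lf must lie in the LF band [0.04, 0.15)", "config_error")
    }
    if (f_hf < 0.15 || f_hf > 0.40) {
      stop_barosens("f_hf must lie in the HF band [0.15, 0.40]", "config_error")
    }
    if (any(c(a_lf, a_hf, rsa_ms, sbp_noise_sd, rr_noise_sd) < 0)) {
      stop_barosens("amplitudes and noise SDs must be >= 0", "config_error")
    }
    if (delay_beats < 0L) {
      stop_barosens("delay_beats must be >= 0", "config_error")
    }
    if (ectopic_rate < 0 || ectopic_rate > 0.5) {
      stop_barosens("ectopic_rate must lie in [0, 0.5]", "config_error")
    }
    # worst plausible deterministic + 5-sigma stochastic RR excursion
    worst <- abs(gain_true) * (a_lf + a_hf + 5 * sbp_noise_sd) +
      rsa_ms + 5 * rr_noise_sd
    if (rr0 / 2 - worst <= 0) {
      stop_barosens("configuration can drive RR <= 0; reduce gain, amplitudes or noise",
                    "config_error")
    }
  })
  invisible(cfg)
}

# deterministic substream seeds derived from the master seed (kept < 2^31)
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1000003) %% 2147483647)
}

#' Simulate a beat series with known baroreflex gain
#'
#' Event-driven generation: at beat k (time `t_k`),
#' `sbp_k = sbp0 + a_lf sin(2 pi f_lf t_k) + a_hf sin(2 pi f_hf t_k) + e_k`
#' and
#' `rr_k = rr0 + gain_true (sbp_(k-delay) - sbp0) + rsa_ms sin(2 pi f_hf t_k) + n_k`,
#' with `t_(k+1) = t_k + rr_k / 1000`. Ectopics are injected by halving the
#' RR of randomly chosen beats (rate `ectopic_rate`); the shortened interval
#' shifts all subsequent beat times, as a premature beat does. Output is
#' bit-identical for a given seed.
#'
#' @param cfg A [sim_config()].
#' @return A list with `series` (a [beat_series]) and `truth` (a list with
#'   `t_s`, noise-free `sbp_mmhg`/`rr_ms`, `ectopic_idx`, `gain_true`,
#'   `delay_beats` and expected per-band RR powers
#'   `expected_lf_power_ms2` / `expected_hf_power_ms2`).
#' @export
simulate_beat_series <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  validate_sim_config(cfg)
  n_max <- ceiling(cfg$duration_s * 1000 / 300) + 10L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, 1L)); eps <- rnorm(n_max, 0, cfg$sbp_noise_sd)
  set.seed(derive_seed(cfg$seed, 2L)); eta <- rnorm(n_max, 0, cfg$rr_noise_sd)
  set.seed(derive_seed(cfg$seed, 3L)); ect_u <- runif(n_max)

  t <- numeric(n_max); sbp <- numeric(n_max); rr <- numeric(n_max)
  sbp_clean <- numeric(n_max); rr_clean <- numeric(n_max)
  is_ect <- logical(n_max)
  t[1L] <- 0
  k <- 0L
  repeat {
    k <- k + 1L
    sbp_clean[k] <- cfg$sbp0 + cfg$a_lf * sin(2 * pi * cfg$f_lf * t[k]) +
      cfg$a_hf * sin(2 * pi * cfg$f_hf * t[k])
    sbp[k] <- sbp_clean[k] + eps[k]
    ref <- if (k > cfg$delay_beats) sbp[k - cfg$delay_beats] else cfg$sbp0
    rr_clean[k] <- cfg$rr0 + cfg$gain_true * (ref - cfg$sbp0) +
      cfg$rsa_ms * sin(2 * pi * cfg$f_hf * t[k])
    rr[k] <- rr_clean[k] + eta[k]
    if (cfg$ectopic_rate > 0 && k > 1L && ect_u[k] < cfg$ectopic_rate) {
      rr[k] <- rr[k] / 2
      is_ect[k] <- TRUE
    }
    if (rr[k] <= 0) {
      stop_barosens("simulation drove RR <= 0; configuration too extreme",
                    "config_error")
    }
    t_next <- t[k] + rr[k] / 1000
    if (t_next > cfg$duration_s || k + 1L > n_max) break
    t[k + 1L] <- t_next
  }
  idx <- seq_len(k)
  series <- new_beat_series(tibble(
    t_s = t[idx],
    rr_ms = rr[idx],
    sbp_mmhg = sbp[idx],
    dbp_mmhg = sbp[idx] - cfg$pulse_pressure,
    map_mmhg = sbp[idx] - 2 * cfg$pulse_pressure / 3,
    valid = rep(TRUE, k)
  ))
  truth <- list(
    t_s = t[idx],
    sbp_mmhg = sbp_clean[idx],
    rr_ms = rr_clean[idx],
    ectopic_idx = which(is_ect[idx]),
    gain_true = cfg$gain_true,
    delay_beats = cfg$delay_beats,
    expected_lf_power_ms2 = (cfg$gain_true * cfg$a_lf)^2 / 2,
    expected_hf_power_ms2 =
      (cfg$rsa_ms + cfg$gain_true * cfg$a_hf)^2 / 2
  )
  list(series = series, truth = truth, config = cfg)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthesize raw waveforms from a beat series
#'
#' Builds stylized but detector-exercising raw channels time-aligned with a
#' beat series: the ECG is a train of Gaussian R waves (20 ms width) at the
#' beat times; the arterial pressure is a per-cycle template rising as a
#' squared half-sine from DBP to the cycle's SBP over the systolic third of
#' the cycle, with a small dicrotic bump in diastole (so the cycle maximum
#' is SBP and the minimum DBP); and the respiratory flow is a sinusoid at
#' `f_resp` whose amplitude delivers the target tidal volume.
#'
#' @param bs A [beat_series].
#' @param fs Output sampling rate in Hz (default 500; must be >= 100).
#' @param f_resp Respiratory frequency of the flow channel, Hz.
#' @param vt_l Target tidal volume, L.
#' @param ecg_snr_db ECG signal-to-noise ratio in dB: white Gaussian noise
#'   is added with power `mean(ecg^2) / 10^(snr/10)`; `Inf` (default) adds
#'   none.
#' @param seed Seed for the ECG noise draw.
#' @return A `waveform_record` with channels `ecg`, `bp`, `flow`.
#' @export
synthesize_waveforms <- function(bs, fs = 500, f_resp = 0.25, vt_l = 0.85,
                                 ecg_snr_db = Inf, seed = 1L) {
  if (fs < 100) {
    stop_barosens("waveform sampling rate must be >= 100 Hz", "config_error")
  }
  t_beats <- c(bs$t_s, attr(bs, "t_end_s", exact = TRUE))
  margin <- 0.5  # s of signal before the first and after the last beat,
                 # as in any real recording; avoids truncated edge beats
  t0 <- t_beats[1L] - margin
  dur <- (t_beats[length(t_beats)] + margin) - t0
  n <- floor(dur * fs) + 1L
  tt <- t0 + (seq_len(n) - 1L) / fs

  # ECG: Gaussian R waves, sigma such that full width ~ 20 ms
  sigma <- 0.020 / 2.355  # FWHM 20 ms
  ecg <- numeric(n)
  for (tb in t_beats) {
    lo <- max(1L, as.integer(floor((tb - t0 - 5 * sigma) * fs)) + 1L)
    hi <- min(n, as.integer(ceiling((tb - t0 + 5 * sigma) * fs)) + 1L)
    if (hi >= lo) {
      idx <- lo:hi
      ecg[idx] <- ecg[idx] + exp(-((tt[idx] - tb)^2) / (2 * sigma^2))
    }
  }
  if (is.finite(ecg_snr_db)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, 11L))
    noise_sd <- sqrt(mean(ecg^2) / 10^(ecg_snr_db / 10))
    ecg <- ecg + rnorm(n, 0, noise_sd)
  }

  # arterial pressure template per cycle
  bp <- numeric(n)
  n_cyc <- nrow(bs)
  for (k in seq_len(n_cyc)) {
    lo_t <- t_beats[k]; hi_t <- t_beats[k + 1L]
    i0 <- max(1L, as.integer(floor((lo_t - t0) * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling((hi_t - t0) * fs)) + 1L)
    idx <- i0:i1
    inside <- tt[idx] >= lo_t & tt[idx] < hi_t
    idx <- idx[inside]
    if (!length(idx)) next
    u <- (tt[idx] - lo_t) / (hi_t - lo_t)  # cycle phase in [0,1)
    pp <- bs$sbp_mmhg[k] - bs$dbp_mmhg[k]
    t_sys <- 1 / 3
    p <- ifelse(u < t_sys,
                sin(pi * u / t_sys)^2,
                0.12 * exp(-(u - t_sys) / 0.25) *
                  sin(pi * (u - t_sys) / (1 - t_sys))^2)
    bp[idx] <- bs$dbp_mmhg[k] + pp * p
  }
  # pad the margins with the neighbouring cycle's DBP
  bp[tt < t_beats[1L]] <- bs$dbp_mmhg[1L]
  bp[tt >= t_beats[length(t_beats)]] <- bs$dbp_mmhg[n_cyc]

  amp <- vt_l * pi * f_resp
  flow <- amp * sin(2 * pi * f_resp * tt)

  new_waveform_record(
    tibble(t_s = tt, ecg = ecg, bp = bp, flow = flow),
    fs = fs, t0 = t0,
    meta = list(synthetic = TRUE, f_resp_hz = f_resp, vt_l = vt_l)
  )
}

#' Condition presets for the simulator
#'
#' Presets encode the direction and magnitude of the group-mean resting
#' values observed before and during a hypobaric-hypoxia sojourn
#' (normoxic baseline `day0`; after ~8 h, `day1`; after 4 days, `day4`),
#' plus acute inspiratory-oxygen restoration (`hyperoxia`) and
#' voluntarily slowed breathing (`controlled`). Relative to baseline,
#' hypoxia raises heart rate (shorter RR), lowers the programmed
#' baroreflex gain and shrinks respiratory sinus arrhythmia (lower HF
#' power); hyperoxia restores most of the gain; controlled breathing
#' lowers the respiratory rate and raises systolic pressure with the
#' gain unchanged.
#'
#' Preset constants (rr0 ms / gain ms/mmHg / sbp0 mmHg / f_hf Hz /
#' rsa ms): day0 890/12.5/126/0.233/62; day1 740/8.9/123/0.267/33;
#' day4 750/7.4/125/0.30/25; hyperoxia 760/10.6/122/0.267/28;
#' controlled 700/8.9/131/0.25/29. All use a 2-beat baroreflex delay.
#'
#' @param name One of `"day0"`, `"day1"`, `"day4"`, `"hyperoxia"`,
#'   `"controlled"`.
#' @param seed Master seed passed through to the config.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A [sim_config()].
#' @export
sim_preset <- function(name, seed = 1L, ...) {
  presets <- list(
    day0 = list(rr0 = 890, gain_true = 12.5, sbp0 = 126,
                f_hf = 14 / 60, rsa_ms = 62, a_lf = 2.5),
    day1 = list(rr0 = 740, gain_true = 8.9, sbp0 = 123,
                f_hf = 16 / 60, rsa_ms = 33, a_lf = 2.8),
    day4 = list(rr0 = 750, gain_true = 7.4, sbp0 = 125,
                f_hf = 18 / 60, rsa_ms = 25, a_lf = 3.2),
    hyperoxia = list(rr0 = 760, gain_true = 10.6, sbp0 = 122,
                     f_hf = 16 / 60, rsa_ms = 28, a_lf = 2.8),
    controlled = list(rr0 = 700, gain_true = 8.9, sbp0 = 131,
                      f_hf = 15 / 60, rsa_ms = 29, a_lf = 2.8)
  )
  if (!name %in% names(presets)) {
    stop_barosens(paste0("unknown preset '", name, "'; valid presets: ",
                         paste(names(presets), collapse = ", ")),
                  "config_error")
  }
  args <- presets[[name]]
  args$delay_beats <- 2L
  args$seed <- seed
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
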