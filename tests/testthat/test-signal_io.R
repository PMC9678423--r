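test_that("waveform reader maps columns, checks finiteness, keeps lengths", {
  tf <- tempfile(fileext = ".tsv")
  set.seed(42)
  n <- 3000
  df <- data.frame(ECG = rnorm(n), Pressure = 90 + rnorm(n), Flow = rnorm(n))
  write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)

  w <- read_waveform_delimited(tf, fs = 1000,
                               column_map = c(ecg = "ECG", bp = "Pressure",
                                              flow = "Flow"))
  expect_setequal(setdiff(names(w), "t_s"), c("ecg", "bp", "flow"))
  expect_equal(nrow(w), n)
  expect_equal(diff(range(w$t_s)), (n - 1) / 1000)
  expect_equal(attr(w, "fs"), 1000)

  expect_error(
    read_waveform_delimited(tf, fs = 1000,
                            column_map = c(ecg = "ECG", bp = "BP")),
    class = "barosens_format_error")

  df_bad <- df
  df_bad$Pressure[17] <- NA
  tf2 <- tempfile(fileext = ".tsv")
  write.table(df_bad, tf2, sep = "\t", row.names = FALSE, quote = FALSE)
  err <- expect_error(
    read_waveform_delimited(tf2, fs = 1000,
                            column_map = c(bp = "Pressure")),
    class = "barosens_data_error")
  expect_match(conditionMessage(err), "17")
})

test_that("waveform write/read round-trip is bit-exact", {
  set.seed(7)
  n <- 500
  w <- barosens:::new_waveform_record(
    tibble::tibble(t_s = (0:(n - 1)) / 250,
                   ecg = rnorm(n), bp = 90 + 30 * runif(n)),
    fs = 250)
  tf <- tempfile(fileext = ".tsv")
  write_waveform_delimited(w, tf)
  w2 <- read_waveform_delimited(tf, fs = 250,
                                column_map = c(ecg = "ecg", bp = "bp"))
  expect_identical(w2$ecg, w$ecg)
  expect_identical(w2$bp, w$bp)
})

test_that("beat table reader flags impossible rows instead of dropping them", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("t_s,rr_ms,sbp_mmhg,dbp_mmhg,map_mmhg",
               "0,800,120,70,88",
               "0.8,-5,121,71,89",
               "1.6,810,122,72,90",
               "2.4,790,60,75,68"), tf)
  bs <- read_beat_table(tf)
  expect_s3_class(bs, "beat_series")
  expect_equal(nrow(bs), 4)          # nothing dropped
  expect_equal(bs$valid, c(TRUE, FALSE, TRUE, FALSE))  # rr<=0, sbp<=dbp

  tf2 <- tempfile(fileext = ".csv")
  writeLines(c("t_s,rr_ms,sbp_mmhg,dbp_mmhg,map_mmhg",
               "0,800,120,70,88",
               "0.9,800,120,70,88",
               "0.5,800,120,70,88"), tf2)
  err <- expect_error(read_beat_table(tf2), class = "barosens_format_error")
  expect_match(conditionMessage(err), "3")
})

test_that("beat table round-trip preserves values to 1e-9", {
  sim <- simulate_beat_series(sim_config(duration_s = 60, seed = 11))
  tf <- tempfile(fileext = ".csv")
  write_beat_table(sim$series, tf)
  back <- read_beat_table(tf)
  for (col in c("t_s", "rr_ms", "sbp_mmhg", "dbp_mmhg", "map_mmhg")) {
    expect_equal(back[[col]], sim$series[[col]], tolerance = 1e-9)
  }
  expect_equal(back$valid, sim$series$valid)
})

test_that("missing beat-table fields become invalid-flagged beats", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("t_s,rr_ms,sbp_mmhg,dbp_mmhg,map_mmhg",
               "0,800,120,70,88",
               "0.8,,121,71,89",
               "1.6,810,122,72,90"), tf)
  bs <- read_beat_table(tf)
  expect_equal(nrow(bs), 3)
  expect_equal(bs$valid, c(TRUE, FALSE, TRUE))
})

test_that("session results serialize with documented keys and schema", {
  sim <- simulate_beat_series(sim_config(seed = 2))
  res <- analyze_session(sim$series,
                         meta = list(participant = "p01", day = "day0",
                                     trial = "spontaneous", spo2_pct = 97))
  jf <- tempfile(fileext = ".json")
  write_results(res, jf, format = "json")
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$cbrs$cbrs_lf_gain_ms_per_mmhg,
               res$tf$cbrs_lf_gain_ms_per_mmhg, tolerance = 1e-12)
  expect_equal(parsed$meta$participant, "p01")
  expect_true(all(c("meta", "suitability", "hemodynamics", "cbrs", "hrv",
                    "settings") %in% names(parsed)))

  cf <- tempfile(fileext = ".csv")
  write_results(res, cf, format = "csv")
  row <- utils::read.csv(cf, check.names = FALSE)
  expect_equal(ncol(row), length(session_result_schema()))
  expect_identical(names(row), session_result_schema())

  expect_error(write_results(res, tempfile(), format = "xml"),
               class = "barosens_format_error")
})

test_that("per-frequency spectra export has the documented columns", {
  sim <- simulate_beat_series(sim_config(seed = 4))
  res <- analyze_session(sim$series)
  sf <- tempfile(fileext = ".csv")
  write_spectra_csv(res$tf, sf)
  sp <- utils::read.csv(sf)
  expect_identical(names(sp), c("freq_hz", "sxx_mmhg2_hz", "syy_ms2_hz",
                                "gain_ms_per_mmhg", "phase_rad", "coherence"))
  expect_gt(nrow(sp), 100)
})
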