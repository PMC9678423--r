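press_tbl <- function(n, sbp = 120, dbp = 75) {
  tibble::tibble(sbp_mmhg = rep(sbp, n), dbp_mmhg = rep(dbp, n),
                 map_mmhg = rep(dbp + (sbp - dbp) / 3, n),
                 valid = rep(TRUE, n))
}

test_that("RR intervals and pairing follow the alignment contract", {
  bs <- build_beat_series(c(0, 0.8, 1.6, 2.4), press_tbl(3), min_beats = 4)
  expect_equal(bs$rr_ms, c(800, 800, 800))
  expect_equal(nrow(bs), 3)

  # off-by-one contract: n beats -> n-1 cycles, first n-1 pressures used
  p <- press_tbl(2)
  p$sbp_mmhg <- c(111, 122)
  bs3 <- build_beat_series(c(0, 0.8, 1.7), p, min_beats = 3)
  expect_equal(bs3$rr_ms, c(800, 900))
  expect_equal(bs3$sbp_mmhg, c(111, 122))

  expect_error(build_beat_series(c(0, 0.8, 1.6), press_tbl(2)),
               class = "barosens_insufficient_data_error")
})

test_that("pairing reproduces the simulator's (sbp_k, rr_k) couples", {
  sim <- simulate_beat_series(sim_config(duration_s = 120, seed = 6))
  s <- sim$series
  beats <- c(s$t_s, attr(s, "t_end_s"))
  rebuilt <- build_beat_series(beats, s[, c("sbp_mmhg", "dbp_mmhg",
                                            "map_mmhg", "valid")])
  expect_equal(rebuilt$rr_ms, s$rr_ms, tolerance = 1e-9)
  expect_equal(rebuilt$sbp_mmhg, s$sbp_mmhg)
})

test_that("a halved RR interval among regular beats is the one flagged", {
  rr <- rep(800, 11)
  rr[6] <- 400
  t <- c(0, cumsum(rr[-11]) / 1000)
  bs <- new_beat_series(tibble::tibble(
    t_s = t, rr_ms = rr, sbp_mmhg = 120, dbp_mmhg = 75, map_mmhg = 90,
    valid = TRUE))
  out <- flag_artifacts(bs)
  expect_equal(which(!out$valid), 6L)
  expect_equal(ectopic_fraction(out), 1 / 11)

  const <- flag_artifacts(make_constant_series(50))
  expect_equal(ectopic_fraction(const), 0)
})

test_that("injected ectopics are recovered with high recall, few false alarms", {
  tp <- fp <- pos <- neg <- 0
  for (seed in 1:10) {
    sim <- simulate_beat_series(sim_config(ectopic_rate = 0.03, seed = seed))
    flagged <- flag_artifacts(sim$series)
    hits <- which(!flagged$valid)
    truth <- sim$truth$ectopic_idx
    tp <- tp + length(intersect(hits, truth))
    fp <- fp + length(setdiff(hits, truth))
    pos <- pos + length(truth)
    neg <- neg + nrow(sim$series) - length(truth)
  }
  expect_gte(tp / pos, 0.95)
  expect_lte(fp / neg, 0.01)
})

test_that("suitability uses an inclusive 5% ceiling", {
  s <- make_constant_series(100)
  attr(s, "ectopic_fraction") <- 0.02
  expect_true(assess_suitability(s)$suitable)
  attr(s, "ectopic_fraction") <- 0.05
  expect_true(assess_suitability(s)$suitable)   # boundary: <= semantics
  attr(s, "ectopic_fraction") <- 0.10
  bad <- assess_suitability(s)
  expect_false(bad$suitable)
  expect_match(bad$reason, "ectop")
  expect_error(assess_suitability(make_constant_series(10)),
               class = "barosens_config_error")
})

test_that("spline resampling reproduces constants and lines exactly", {
  s <- make_constant_series(100)
  eq <- interpolate_resample(s, "rr")
  expect_true(all(eq$value == 800))
  expect_equal(diff(eq$t_s), rep(0.25, nrow(eq) - 1), tolerance = 1e-12)

  lin <- make_constant_series(100)
  lin$rr_ms <- 700 + 2 * lin$t_s
  eq2 <- interpolate_resample(new_beat_series(lin), "rr")
  expect_equal(eq2$value, 700 + 2 * eq2$t_s, tolerance = 1e-9)
})

test_that("resampling preserves a 0.1 Hz oscillation amplitude within 2%", {
  t <- cumsum(rep(0.8, 380)); t <- c(0, t[-380])
  rr <- 800 + 50 * sin(2 * pi * 0.1 * t)
  s <- new_beat_series(tibble::tibble(
    t_s = t, rr_ms = rr, sbp_mmhg = 120, dbp_mmhg = 75, map_mmhg = 90,
    valid = TRUE))
  eq <- interpolate_resample(s, "rr")
  # amplitude via least squares on the quadrature pair at 0.1 Hz
  X <- cbind(sin(2 * pi * 0.1 * eq$t_s), cos(2 * pi * 0.1 * eq$t_s))
  beta <- qr.solve(X, eq$value - mean(eq$value))
  expect_equal(sqrt(sum(beta^2)), 50, tolerance = 0.02)
})

test_that("resampling ignores flagged beats and never extrapolates", {
  sim <- simulate_beat_series(sim_config(duration_s = 120, seed = 13))
  s <- sim$series
  eq0 <- interpolate_resample(s, "rr")

  # a flagged beat's value is arbitrary: any value gives identical output
  s2 <- s
  s2$valid[100] <- FALSE
  s2$rr_ms[100] <- 5000
  s3 <- s2
  s3$rr_ms[100] <- -12345
  eq2 <- interpolate_resample(s2, "rr")
  eq3 <- interpolate_resample(s3, "rr")
  expect_identical(eq2$value, eq3$value)

  keep <- s2$valid
  expect_true(all(eq2$t_s >= min(s2$t_s[keep]) - 1e-12))
  expect_true(all(eq2$t_s <= max(s2$t_s[keep]) + 1e-12))

  # mean preservation for a stationary series
  expect_equal(mean(eq0$value), mean(s$rr_ms), tolerance = 0.01)

  expect_error(interpolate_resample(make_constant_series(3), "rr"),
               class = "barosens_insufficient_data_error")
})
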