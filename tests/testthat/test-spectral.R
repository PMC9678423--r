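test_that("segmentation arithmetic: 5-min record at 4 Hz gives 100-s segments", {
  x <- rnorm(1200)
  s <- welch_cross_spectra(x, x, fs = 4)
  expect_equal(attr(s, "segment_len_s"), 100)
  expect_equal(s$freq_hz[2] - s$freq_hz[1], 0.01)
  expect_equal(attr(s, "n_segments"), 5L)

  expect_error(welch_cross_spectra(rnorm(50), rnorm(50), fs = 4),
               class = "barosens_insufficient_data_error")
})

test_that("identity input gives unit gain and coherence everywhere", {
  set.seed(21)
  x <- rnorm(600)
  tf <- transfer_function(welch_cross_spectra(x, x, fs = 4))
  sp <- tf$spectra[tf$spectra$freq_hz > 0, ]
  expect_equal(sp$gain_ms_per_mmhg, rep(1, nrow(sp)), tolerance = 1e-9)
  expect_equal(sp$coherence, rep(1, nrow(sp)), tolerance = 1e-9)
  expect_equal(sp$phase_rad, rep(0, nrow(sp)), tolerance = 1e-9)
})

test_that("production Welch equals the brute-force DFT oracle to 1e-9", {
  set.seed(5)
  for (case in list(list(n = 300, k = 5L), list(n = 512, k = 5L),
                    list(n = 200, k = 3L))) {
    x <- rnorm(case$n)
    y <- 0.5 * x + rnorm(case$n)
    s <- welch_cross_spectra(x, y, fs = 4, n_segments = case$k)
    o <- oracle_welch(x, y, fs = 4, K = case$k)
    expect_equal(s$freq_hz, o$freq, tolerance = 1e-12)
    expect_equal(s$sxx, o$sxx, tolerance = 1e-9)
    expect_equal(s$syy, o$syy, tolerance = 1e-9)
    expect_equal(Mod(s$sxy - o$sxy) / pmax(Mod(o$sxy), 1e-12),
                 rep(0, length(o$sxy)), tolerance = 1e-9)
  }
})

test_that("a pure delay line is recovered at its drive frequency", {
  t <- (0:1199) / 4
  x <- sin(2 * pi * 0.10 * t)
  y <- 8 * sin(2 * pi * 0.10 * (t - 1.5))
  tf <- transfer_function(welch_cross_spectra(x, y, fs = 4))
  i <- which.min(abs(tf$spectra$freq_hz - 0.10))
  expect_equal(tf$spectra$freq_hz[i], 0.10)
  expect_equal(tf$spectra$gain_ms_per_mmhg[i], 8, tolerance = 0.01)
  expect_equal(tf$spectra$phase_rad[i], -2 * pi * 0.10 * 1.5,
               tolerance = 0.05)
  expect_gt(tf$spectra$coherence[i], 0.99)
})

test_that("conjugating the cross-spectrum flips phase and keeps gain", {
  set.seed(9)
  x <- rnorm(600)
  y <- stats::filter(x, rep(0.3, 3), sides = 1)
  y[is.na(y)] <- 0
  s <- welch_cross_spectra(x, as.numeric(y), fs = 4)
  s2 <- s
  s2$sxy <- Conj(s$sxy)
  tf1 <- transfer_function(s)
  tf2 <- transfer_function(s2)
  sel <- !is.na(tf1$spectra$phase_rad) &
    abs(abs(tf1$spectra$phase_rad) - pi) > 1e-6
  expect_equal(tf2$spectra$phase_rad[sel], -tf1$spectra$phase_rad[sel],
               tolerance = 1e-12)
  expect_equal(tf2$spectra$gain_ms_per_mmhg, tf1$spectra$gain_ms_per_mmhg,
               tolerance = 1e-12)
})

test_that("band membership follows the half-open edge convention", {
  x <- rnorm(1200)
  tf <- transfer_function(welch_cross_spectra(x, x, fs = 4))
  # 0.01 Hz resolution: LF = 0.04..0.14 inclusive, 11 bins
  lf <- tf$bands[tf$bands$band == "lf", ]
  expect_equal(lf$n_bins, 11L)
  vlf <- tf$bands[tf$bands$band == "vlf", ]
  expect_equal(vlf$n_bins, 3L)   # 0.01, 0.02, 0.03 (DC excluded)
  hf <- tf$bands[tf$bands$band == "hf", ]
  expect_equal(hf$n_bins, 26L)   # 0.15..0.40 inclusive
})

test_that("constant gain across the LF band is reported as the cBRS index", {
  set.seed(33)
  x <- rnorm(1200)
  tf <- transfer_function(welch_cross_spectra(x, 7.4 * x, fs = 4))
  expect_equal(tf$cbrs_lf_gain_ms_per_mmhg, 7.4, tolerance = 1e-9)
  expect_equal(tf$bands$gain_ms_per_mmhg[tf$bands$band == "lf"],
               tf$cbrs_lf_gain_ms_per_mmhg)
})

test_that("coherence of independent noise shows only the K-average bias", {
  set.seed(14)
  mean_lf_coh <- mean(replicate(10, {
    x <- rnorm(1200)
    y <- rnorm(1200)
    tf <- transfer_function(welch_cross_spectra(x, y, fs = 4))
    tf$bands$coherence[tf$bands$band == "lf"]
  }))
  expect_lt(mean_lf_coh, 0.45)
  expect_gt(mean_lf_coh, 0.05)  # the bias floor for 5 averaged segments
})

test_that("coherence stays in [0,1] and obeys Cauchy-Schwarz on random input", {
  set.seed(77)
  for (i in 1:20) {
    x <- rnorm(400) * runif(1, 0.1, 50)
    y <- rnorm(400) * runif(1, 0.1, 50) + runif(1, -1, 1) * x
    s <- welch_cross_spectra(x, y, fs = 4)
    expect_true(all(Mod(s$sxy)^2 <= s$sxx * s$syy * (1 + 1e-12)))
    coh <- transfer_function(s)$spectra$coherence
    coh <- coh[!is.na(coh)]
    expect_true(all(coh >= 0 & coh <= 1 + 1e-12))
  }
})

test_that("detrending makes gain invariant to constant offsets", {
  set.seed(55)
  x <- rnorm(800)
  y <- 3 * x + rnorm(800, sd = 0.1)
  tf1 <- transfer_function(welch_cross_spectra(x, y, fs = 4))
  tf2 <- transfer_function(welch_cross_spectra(x + 120, y + 800, fs = 4))
  expect_equal(tf2$spectra$gain_ms_per_mmhg, tf1$spectra$gain_ms_per_mmhg,
               tolerance = 1e-9)
})

test_that("integrated RR autospectrum matches the detrended variance", {
  set.seed(101)
  errs <- replicate(20, {
    z <- rnorm(1200, sd = runif(1, 0.5, 40))
    s <- welch_cross_spectra(z, z, fs = 4)
    oracle_integrate(s$freq_hz, s$syy) / oracle_segment_variance(z) - 1
  })
  expect_lt(max(abs(errs)), 0.05)
})

test_that("a zero autospectrum yields missing gain, never infinities", {
  x <- rep(5, 400)       # constant SBP: all spectral mass removed by detrend
  y <- rnorm(400)
  tf <- transfer_function(welch_cross_spectra(x, y, fs = 4))
  expect_true(all(is.na(tf$spectra$gain_ms_per_mmhg)))
  expect_true(is.na(tf$cbrs_lf_gain_ms_per_mmhg))
  expect_false(any(is.infinite(tf$spectra$gain_ms_per_mmhg)))
})

test_that("coherence gating reports contributing bins and can empty a band", {
  set.seed(70)
  x <- rnorm(1200)
  y <- rnorm(1200)
  s <- welch_cross_spectra(x, y, fs = 4)
  gated <- transfer_function(s, coherence_min = 0.999)
  lf <- gated$bands[gated$bands$band == "lf", ]
  expect_true(lf$n_bins < 11L)
  if (lf$n_bins == 0L) expect_true(is.na(lf$gain_ms_per_mmhg))
})
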