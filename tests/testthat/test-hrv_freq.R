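test_that("cubic-spline resampling interpolates the tachogram", {
  rr <- rr_series(rep(1000, 20))
  tac <- resample_rr(rr, target_fs = 4)
  expect_true(all(abs(tac$rr - 1000) < 1e-9))
  # grid arithmetic
  bt <- rr$beat_times[-1]
  expect_length(tac$t, floor((bt[20] - bt[1]) * 4) + 1)
  # interpolant passes through the knots
  set.seed(3)
  x <- 900 + rnorm(30, 0, 30)
  rr2 <- rr_series(x)
  tac2 <- resample_rr(rr2, target_fs = 8)
  bt2 <- rr2$beat_times[-1]
  on_grid <- bt2[(bt2 - bt2[1]) * 8 %% 1 == 0]
  if (length(on_grid)) {
    at <- stats::spline(bt2, x, xout = on_grid)$y
    expect_equal(at, x[match(on_grid, bt2)], tolerance = 1e-9)
  }
  expect_error(resample_rr(rr_series(c(800, 810, 790))), "insufficient")
})

test_that("Welch spectrum localizes a 0.1 Hz oscillation", {
  rr <- synth_rr_series(400, mean_rr = 800, lf_amp = 50, hf_amp = 0,
                        ar_sd = 1, seed = 8)
  tac <- resample_rr(rr)
  spec <- welch_psd(tac)
  peak_f <- spec$freqs[which.max(spec$psd)]
  df <- spec$freqs[2] - spec$freqs[1]
  expect_lte(abs(peak_f - 0.1), df)
  expect_true(all(spec$psd >= 0))
})

test_that("Welch PSD integral matches the variance of white noise", {
  set.seed(77)
  x <- rnorm(2048, 0, 30)
  spec <- welch_psd(x, fs = 4)
  df <- diff(spec$freqs[1:2])
  expect_equal(sum(spec$psd) * df, var(x), tolerance = 0.1 * var(x))
  # zero-variance input has (numerically) no power
  spec0 <- welch_psd(rep(5, 512), fs = 4)
  expect_true(all(spec0$psd < 1e-20))
  expect_error(welch_psd(rnorm(100), fs = 4), "insufficient")
})

test_that("AR spectrum resolves a resonance and stays nonnegative", {
  # AR(2) with poles at 0.1 Hz under fs = 4
  f0 <- 0.1; fs <- 4; rho <- 0.95
  a <- c(2 * rho * cos(2 * pi * f0 / fs), -rho^2)
  set.seed(6)
  x <- as.numeric(stats::filter(rnorm(4096), a, method = "recursive"))
  spec <- ar_psd(x, fs = fs, order = 16)
  expect_lte(abs(spec$freqs[which.max(spec$psd)] - 0.1), 0.01)
  expect_true(all(spec$psd >= 0))
  expect_error(ar_psd(rnorm(10), fs = 4, order = 16), "configuration")
})

test_that("AR spectrum of white noise is approximately flat", {
  set.seed(15)
  ratios <- replicate(6, {
    spec <- ar_psd(rnorm(2048), fs = 4, order = 16)
    band <- spec$psd[spec$freqs >= 0.04 & spec$freqs <= 0.4]
    max(band) / min(band)
  })
  expect_lt(mean(ratios), 10)
})

test_that("band powers integrate additively and normalize to one", {
  rr <- synth_rr_series(400, mean_rr = 800, lf_amp = 50, hf_amp = 0,
                        ar_sd = 1, seed = 8)
  bp <- freq_domain_features(rr)
  expect_gt(bp$LFpower / bp$TP, 0.9)
  expect_gt(bp$LF_HF, 1)
  expect_equal(bp$nLF + bp$nHF, 1, tolerance = 1e-9)
  expect_equal(bp$TP, bp$VLFpower + bp$LFpower + bp$HFpower)
  # degenerate zero spectrum
  spec0 <- structure(list(freqs = seq(0, 0.5, by = 0.01),
                          psd = rep(0, 51), method = "welch"),
                     class = "spectral_estimate")
  b0 <- band_powers(spec0)
  expect_equal(b0$TP, 0)
  expect_true(is.na(b0$LF_HF))
  spec_short <- structure(list(freqs = seq(0, 0.3, by = 0.01),
                               psd = rep(1, 31), method = "welch"),
                          class = "spectral_estimate")
  expect_error(band_powers(spec_short), "domain error")
})

test_that("Welch and AR agree on which band dominates", {
  for (sd_seed in 1:3) {
    rr_lf <- synth_rr_series(300, lf_amp = 40, hf_amp = 2, ar_sd = 2,
                             seed = sd_seed)
    rr_hf <- synth_rr_series(300, lf_amp = 2, hf_amp = 40, ar_sd = 2,
                             seed = sd_seed)
    for (est in c("welch", "ar")) {
      lf <- freq_domain_features(rr_lf, estimator = est)
      hf <- freq_domain_features(rr_hf, estimator = est)
      expect_gt(lf$LFpower, lf$HFpower)
      expect_gt(hf$HFpower, hf$LFpower)
    }
  }
})

test_that("doubling tachogram amplitude quadruples band powers", {
  rr <- synth_rr_series(300, lf_amp = 20, hf_amp = 20, ar_sd = 5, seed = 4)
  base <- freq_domain_features(rr)
  rr2 <- rr_series(2 * (rr$intervals - mean(rr$intervals)) +
                     mean(rr$intervals), beat_times = rr$beat_times)
  dbl <- freq_domain_features(rr2)
  expect_equal(dbl$LFpower / base$LFpower, 4, tolerance = 0.05)
  expect_equal(dbl$HFpower / base$HFpower, 4, tolerance = 0.05)
  expect_equal(dbl$nLF, base$nLF, tolerance = 0.02)
})
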