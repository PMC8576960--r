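rec60 <- make_clean_record(duration = 60)
truth60 <- attr(rec60, "truth")

test_that("R-peaks on a 1 Hz synthetic rhythm are recovered beat for beat", {
  pk <- detect_r_peaks(rec60)
  expect_true(abs(length(pk) - 60) <= 1)
  k <- min(length(pk), length(truth60$r_peaks))
  expect_true(max(abs(pk[seq_len(k)] - truth60$r_peaks[seq_len(k)])) <= 3)
  expect_true(all(diff(pk) > 0))
  # implied HR within physiological bounds
  hr <- 60 / diff(pk / rec60$fs)
  expect_true(all(hr >= 20 & hr <= 300))
})

test_that("flat signal raises a detection error", {
  flat <- ecg_record(rep(0, 128 * 15), fs = 128)
  expect_error(detect_r_peaks(flat), "detection error")
  expect_error(detect_r_peaks(ecg_record(rep(0.1, 128 * 5), fs = 128)),
               "10 s")
})

test_that("P-wave width is recovered within 2 samples on noiseless beats", {
  # ~110 ms wide P-wave: width parameter chosen so the 5% support is 110 ms
  w_ms <- 110 / (2 * sqrt(log(20)))
  rec <- make_clean_record(duration = 60, params = list(
    p_amp_mv = 0.2, p_width_ms = w_ms, mean_rr_ms = 1000,
    lf_amp_ms = 0, hf_amp_ms = 0, ar_sd_ms = 0, shuffle_frac = 0))
  pk <- detect_r_peaks(rec)
  fid <- delineate_p_wave(rec, pk)
  pw <- pwave_basic_features(rec, fid)
  expect_lt(abs(pw$PW - 110), 2 / rec$fs * 1000)
  # PD: onset-to-peak of a symmetric wave is half the width
  expect_lt(abs(pw$PD - 55), 2 / rec$fs * 1000)
  expect_lt(abs(pw$PA - 0.2), 0.01)
})

test_that("fiducial ordering holds for every retained beat", {
  rec <- synth_record("ord", duration = 120, seed = 5,
                      params = list(p_amp_mv = 0.15, p_width_ms = 29,
                                    mean_rr_ms = 800, lf_amp_ms = 15,
                                    hf_amp_ms = 20, ar_sd_ms = 30,
                                    shuffle_frac = 0))
  fid <- delineate_p_wave(rec, detect_r_peaks(rec))
  expect_true(all(fid$p_onset < fid$p_peak))
  expect_true(all(fid$p_peak < fid$p_offset))
  expect_true(all(fid$p_offset < fid$r_peaks))
  df <- as.data.frame(fid)
  expect_named(df, c("beat", "r_peak", "p_onset", "p_peak", "p_offset"))
})

test_that("beats with no P-wave are dropped, all-failed raises", {
  rec <- make_clean_record(duration = 60, params = list(
    p_amp_mv = 0.001, p_width_ms = 29, mean_rr_ms = 1000,
    lf_amp_ms = 0, hf_amp_ms = 0, ar_sd_ms = 0, shuffle_frac = 0))
  pk <- detect_r_peaks(rec)
  expect_error(delineate_p_wave(rec, pk), "delineation error")
})

test_that("recovered PW tracks the generating width monotonically", {
  pw_at <- function(w_ms) {
    rec <- make_clean_record(duration = 40, params = list(
      p_amp_mv = 0.15, p_width_ms = w_ms, mean_rr_ms = 900,
      lf_amp_ms = 0, hf_amp_ms = 0, ar_sd_ms = 0, shuffle_frac = 0))
    pk <- detect_r_peaks(rec)
    pwave_basic_features(rec, delineate_p_wave(rec, pk))$PW
  }
  widths <- vapply(c(20, 29, 38), pw_at, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("direct P parameters follow their defining arithmetic", {
  # constructed fiducials on a flat-baseline record
  x <- rep(0, 256)
  x[108] <- 0.15
  rec <- ecg_record(x, fs = 128)
  fid <- fiducial_set(r_peaks = 140, p_onset = 100, p_peak = 108,
                      p_offset = 114, baseline = 0)
  pb <- pwave_basic_features(rec, fid)
  expect_equal(pb$PW, (114 - 100) / 128 * 1000)  # 109.375 ms
  expect_equal(pb$PD, (108 - 100) / 128 * 1000)  # 62.5 ms
  expect_equal(pb$PA, 0.15)
  # subject-level aggregation is the median across beats
  fid3 <- fiducial_set(r_peaks = c(40, 90, 140) + 20,
                       p_onset = c(10, 60, 110),
                       p_peak = c(15, 66, 118),
                       p_offset = c(22, 74, 125), baseline = rep(0, 3))
  pb3 <- pwave_basic_features(rec, fid3)
  expect_equal(pb3$PW, stats::median((c(12, 14, 15)) / 128 * 1000))
  expect_error(pwave_basic_features(rec, fiducial_set(integer(0), integer(0),
                                                      integer(0), integer(0))),
               "insufficient")
  expect_error(fiducial_set(10, 20, 25, 30), "ordering")
})
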