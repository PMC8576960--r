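#' Resample an RR series to a uniform tachogram
#'
#' Cubic-spline interpolation of interval value against beat time,
#' sampled on a uniform grid at `target_fs` between the first and last
#' beat time (no extrapolation). Each interval is attributed to the time
#' of its terminating beat.
#'
#' @param rr An [rr_series()] with at least 4 intervals.
#' @param target_fs Resampling rate in Hz (default 4, standard HRV
#'   practice).
#' @return A list of class `tachogram`: `t` (s), `rr` (ms), `fs`.
#' @export
resample_rr <- function(rr, target_fs = 4) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  if (length(x) < 4L)
    stopf("insufficient data: need at least 4 beats for cubic-spline resampling")
  bt <- if (length(rr$beat_times) == length(x) + 1L)
    rr$beat_times[-1L] else rr$beat_times
  grid <- bt[1L] + (0:floor((bt[length(bt)] - bt[1L]) * target_fs)) / target_fs
  y <- stats::spline(bt, x, xout = grid, method = "fmm")$y
  structure(list(t = grid, rr = y, fs = target_fs), class = "tachogram")
}

#' Welch periodogram of a uniformly sampled tachogram
#'
#' The series is divided into overlapping segments, each mean-detrended
#' and Hann-windowed; the one-sided PSD is the average of the segment
#' periodograms, scaled so that its integral approximates the series
#' variance (Parseval consistency).
#'
#' @param x Numeric series (ms) or a `tachogram` from [resample_rr()].
#' @param fs Sampling rate in Hz (taken from the tachogram if given).
#' @param segment_length Samples per segment (default 256, i.e. 64 s at
#'   4 Hz).
#' @param overlap Fractional overlap between segments.
#' @return A list of class `spectral_estimate`: `freqs` (Hz), `psd`
#'   (ms^2/Hz), `method = "welch"`.
#' @export
welch_psd <- function(x, fs = NULL, segment_length = 256, overlap = 0.5) {
  if (inherits(x, "tachogram")) { fs <- x$fs; x <- x$rr }
  assert_scalar_num(fs, "fs", positive = TRUE)
  n <- length(x)
  L <- as.integer(segment_length)
  if (n < L)
    stopf("insufficient data: tachogram shorter than one Welch segment (%d < %d)",
          n, L)
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))      # Hann
  scale <- fs * sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / scale
    P <- P[seq_len(nf)]
    P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)]
    acc <- acc + P
  }
  structure(list(freqs = (seq_len(nf) - 1L) * fs / L,
                 psd = acc / length(starts), method = "welch"),
            class = "spectral_estimate")
}

#' Autoregressive (Burg) spectral estimate of a tachogram
#'
#' Fits an AR model of fixed order by Burg's method and evaluates the
#' one-sided parametric PSD on a dense frequency grid.
#'
#' @param x Numeric series (ms) or a `tachogram`.
#' @param fs Sampling rate in Hz.
#' @param order AR model order (default 16, the HRV-literature default).
#' @param n_freq Number of grid points on `[0, fs/2]`.
#' @return A `spectral_estimate` with `method = "ar"`.
#' @export
ar_psd <- function(x, fs = NULL, order = 16, n_freq = 513) {
  if (inherits(x, "tachogram")) { fs <- x$fs; x <- x$rr }
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (order >= length(x))
    stopf("configuration error: AR order (%d) must be below series length (%d)",
          order, length(x))
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  freqs <- seq(0, fs / 2, length.out = n_freq)
  z <- exp(-2i * pi * outer(freqs / fs, seq_along(a)))
  denom <- Mod(1 - drop(z %*% a))^2
  psd <- 2 * fit$var.pred / fs / denom
  psd[c(1L, n_freq)] <- psd[c(1L, n_freq)] / 2
  structure(list(freqs = freqs, psd = psd, method = "ar"),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("Spectral estimate (%s): %d bins on [0, %.3g] Hz\n",
              x$method, length(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Frequency-band powers of an RR spectral estimate
#'
#' Trapezoidal integration of the PSD over the standard short-term HRV
#' bands VLF `[0, 0.04)`, LF `[0.04, 0.15)` and HF `[0.15, 0.4]` Hz, with
#' the PSD linearly interpolated at the exact band edges so the bands
#' tile `[0, 0.4]` additively. Total power `TP = VLF + LF + HF`;
#' normalized powers `nLF = LF/(TP - VLF)`, `nHF = HF/(TP - VLF)` (which
#' sum to 1); `LF/HF` is reported missing when HF power is 0.
#'
#' @param spec A `spectral_estimate` whose grid covers `[0, 0.4]` Hz.
#' @return A list of class `hrv_freq` with `VLFpower`, `LFpower`,
#'   `HFpower`, `LF_HF`, `TP`, `nLF`, `nHF` (powers in ms^2).
#' @export
band_powers <- function(spec) {
  stopifnot(inherits(spec, "spectral_estimate"))
  if (max(spec$freqs) < 0.4)
    stopf("domain error: frequency grid must cover [0, 0.4] Hz")
  band <- function(f0, f1) {
    f <- spec$freqs
    inner <- f > f0 & f < f1
    fx <- c(f0, f[inner], f1)
    px <- stats::approx(f, spec$psd, xout = fx, rule = 2)$y
    sum(diff(fx) * (px[-1] + px[-length(px)]) / 2)
  }
  vlf <- band(0, 0.04); lf <- band(0.04, 0.15); hf <- band(0.15, 0.4)
  tp <- vlf + lf + hf
  structure(list(
    VLFpower = vlf, LFpower = lf, HFpower = hf,
    LF_HF = if (hf > 0) lf / hf else NA_real_,
    TP = tp,
    nLF = if (tp - vlf > 0) lf / (tp - vlf) else NA_real_,
    nHF = if (tp - vlf > 0) hf / (tp - vlf) else NA_real_
  ), class = "hrv_freq")
}

#' Frequency-domain HRV parameters from an RR series
#'
#' Convenience pipeline: [resample_rr()] at `target_fs`, spectral
#' estimation by Welch (default) or Burg AR, then [band_powers()].
#'
#' @param rr An [rr_series()].
#' @param estimator `"welch"` or `"ar"`.
#' @param target_fs Resampling rate (Hz).
#' @param segment_length,overlap Welch settings.
#' @param ar_order AR order.
#' @return An `hrv_freq` list, see [band_powers()].
#' @export
freq_domain_features <- function(rr, estimator = c("welch", "ar"),
                                 target_fs = 4, segment_length = 256,
                                 overlap = 0.5, ar_order = 16) {
  estimator <- match.arg(estimator)
  tach <- resample_rr(rr, target_fs)
  spec <- if (estimator == "welch")
    welch_psd(tach, segment_length = segment_length, overlap = overlap)
  else
    ar_psd(tach, order = ar_order)
  band_powers(spec)
}
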