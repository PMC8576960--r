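#' Detect R-peaks in a single-lead ECG
#'
#' Derivative–square–moving-window-integration detector (Pan–Tompkins
#' style): the signal is band-passed 5–15 Hz, differenced, squared and
#' integrated over a 150 ms window; candidate peaks above an adaptive
#' threshold are refined to the local maximum of the raw signal and a
#' 200 ms refractory period is enforced, which keeps the implied
#' instantaneous heart rate inside a physiological range.
#'
#' @param record An [ecg_record()] of at least 10 s.
#' @param refractory_ms Minimum peak-to-peak distance in ms.
#' @return Strictly increasing R-peak sample indices (1-based).
#' @export
detect_r_peaks <- function(record, refractory_ms = 200) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  if (length(x) / fs < 10)
    stopf("record must be at least 10 s long for R-peak detection")
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  d <- c(0, diff(xf))
  z <- stats::filter(d^2, rep(1, max(3L, round(0.150 * fs))), sides = 2)
  z[is.na(z)] <- 0
  z <- as.numeric(z)
  thr <- 0.25 * stats::quantile(z, 0.99, names = FALSE)
  if (!is.finite(thr) || thr <= 1e-10)
    stopf("detection error: no QRS energy found in record '%s'",
          record$subject_id)
  n <- length(z)
  loc <- which(z > thr &
                 z >= c(-Inf, z[-n]) &
                 z >= c(z[-1], -Inf))
  if (length(loc) == 0L)
    stopf("detection error: no peaks above threshold in record '%s'",
          record$subject_id)
  # refine each candidate to the raw-signal maximum nearby
  half <- as.integer(round(0.075 * fs))
  peaks <- vapply(as.integer(loc), function(i) {
    a <- max(1L, i - half); b <- min(n, i + half)
    a + which.max(x[a:b]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refractory filtering: among peaks closer than the refractory period,
  # keep the taller one
  min_gap <- refractory_ms / 1000 * fs
  keep <- logical(length(peaks))
  last <- -Inf
  last_i <- 0L
  for (j in seq_along(peaks)) {
    if (peaks[j] - last >= min_gap) {
      keep[j] <- TRUE
      last <- peaks[j]
      last_i <- j
    } else if (x[peaks[j]] > x[peaks[last_i]]) {
      keep[last_i] <- FALSE
      keep[j] <- TRUE
      last <- peaks[j]
      last_i <- j
    }
  }
  peaks <- peaks[keep]
  if (length(peaks) == 0L)
    stopf("detection error: no peaks retained in record '%s'",
          record$subject_id)
  peaks
}

#' Construct a per-beat fiducial set
#'
#' @param r_peaks,p_onset,p_peak,p_offset Parallel vectors of sample
#'   indices, one entry per retained beat, with
#'   `p_onset < p_peak < p_offset < r_peak` for every beat.
#' @param baseline Optional per-beat baseline amplitude (mV); when absent,
#'   consumers estimate it from the 20 ms preceding `p_onset`.
#' @param n_dropped Number of beats dropped during delineation.
#' @return An object of class `fiducial_set`.
#' @export
fiducial_set <- function(r_peaks, p_onset, p_peak, p_offset,
                         baseline = NULL, n_dropped = 0L) {
  k <- length(r_peaks)
  if (!all(lengths(list(p_onset, p_peak, p_offset)) == k))
    stopf("fiducial vectors must have equal length")
  if (k > 0L && !all(p_onset < p_peak & p_peak < p_offset & p_offset < r_peaks))
    stopf("fiducial ordering violated: need p_onset < p_peak < p_offset < r_peak")
  structure(list(r_peaks = as.integer(r_peaks),
                 p_onset = as.integer(p_onset),
                 p_peak = as.integer(p_peak),
                 p_offset = as.integer(p_offset),
                 baseline = baseline,
                 n_dropped = as.integer(n_dropped)),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("Fiducial set: %d retained beats (%d dropped)\n",
              length(x$r_peaks), x$n_dropped))
  invisible(x)
}

#' @export
as.data.frame.fiducial_set <- function(x, ...) {
  data.frame(beat = seq_along(x$r_peaks), r_peak = x$r_peaks,
             p_onset = x$p_onset, p_peak = x$p_peak, p_offset = x$p_offset)
}

#' Delineate P-waves ahead of detected R-peaks
#'
#' Within a search window before each R-peak (default 250 ms to 60 ms
#' pre-R), the baseline is taken as the median of the window's first
#' 20 ms; the P-peak is the maximum above baseline and onset/offset are
#' the crossings of 5 % of the local P amplitude. Beats whose P amplitude
#' falls below `min_p_amp`, whose onset or offset is not visible inside
#' the window, or that sit within 300 ms of the record boundaries are
#' dropped, not imputed.
#'
#' @param record An [ecg_record()].
#' @param r_peaks R-peak sample indices, e.g. from [detect_r_peaks()].
#' @param search_window `c(start, end)` of the pre-R window in ms before
#'   the R-peak (start > end).
#' @param min_p_amp Minimum baseline-to-peak P amplitude (mV) for a beat
#'   to be retained.
#' @return A [fiducial_set()].
#' @export
delineate_p_wave <- function(record, r_peaks, search_window = c(250, 60),
                             min_p_amp = 0.05) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  n <- length(x)
  w_pre <- round(search_window[1] / 1000 * fs)
  w_post <- round(search_window[2] / 1000 * fs)
  if (w_pre <= w_post)
    stopf("search window start must exceed its end (ms before R)")
  edge <- round(0.300 * fs)
  base_len <- max(1L, round(0.020 * fs))
  on <- pk <- off <- ri <- integer(0)
  bl <- numeric(0)
  dropped <- 0L
  for (r in r_peaks) {
    a <- r - w_pre
    b <- r - w_post
    if (a < 1L || r <= edge || r > n - edge) { dropped <- dropped + 1L; next }
    seg <- x[a:b]
    baseline <- stats::median(seg[seq_len(min(base_len, length(seg)))])
    seg <- seg - baseline
    ip <- which.max(seg)
    amp <- seg[ip]
    if (!is.finite(amp) || amp < min_p_amp) { dropped <- dropped + 1L; next }
    thr <- 0.05 * amp
    below_l <- which(seg[seq_len(ip)] < thr)
    below_r <- which(seg[ip:length(seg)] < thr)
    if (length(below_l) == 0L || length(below_r) == 0L) {
      dropped <- dropped + 1L; next      # onset or offset not in window
    }
    i_on <- max(below_l) + 1L
    i_off <- ip + min(below_r) - 2L
    if (!(i_on < ip && ip < i_off)) { dropped <- dropped + 1L; next }
    on <- c(on, a + i_on - 1L)
    pk <- c(pk, a + ip - 1L)
    off <- c(off, a + i_off - 1L)
    ri <- c(ri, r)
    bl <- c(bl, baseline)
  }
  if (length(ri) == 0L)
    stopf("delineation error: no beat yielded a P-wave in record '%s'",
          record$subject_id)
  fiducial_set(ri, on, pk, off, baseline = bl, n_dropped = dropped)
}

#' Direct P-wave morphology parameters (PW, PA, PD)
#'
#' Per beat: `PW = (p_offset - p_onset)/fs * 1000` ms (wave width),
#' `PA` = amplitude at the P-peak above baseline (mV), and
#' `PD = (p_peak - p_onset)/fs * 1000` ms (onset-to-peak time). The
#' subject-level value of each parameter is the median across retained
#' beats.
#'
#' @param record An [ecg_record()].
#' @param fiducials A [fiducial_set()].
#' @return A list of class `pwave_basic` with subject-level `PW`, `PA`,
#'   `PD` and a `per_beat` data frame.
#' @export
pwave_basic_features <- function(record, fiducials) {
  stopifnot(inherits(record, "ecg_record"), inherits(fiducials, "fiducial_set"))
  if (length(fiducials$r_peaks) == 0L)
    stopf("insufficient data: empty fiducial set")
  fs <- record$fs
  x <- record$samples
  bl <- fiducials$baseline
  if (is.null(bl)) {
    base_len <- max(1L, round(0.020 * fs))
    bl <- vapply(fiducials$p_onset, function(i) {
      a <- max(1L, i - base_len)
      stats::median(x[a:max(a, i - 1L)])
    }, numeric(1))
  }
  pw <- (fiducials$p_offset - fiducials$p_onset) / fs * 1000
  pd <- (fiducials$p_peak - fiducials$p_onset) / fs * 1000
  pa <- x[fiducials$p_peak] - bl
  structure(list(PW = stats::median(pw), PA = stats::median(pa),
                 PD = stats::median(pd),
                 per_beat = data.frame(beat = seq_along(pw),
                                       PW = pw, PA = pa, PD = pd)),
            class = "pwave_basic")
}
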