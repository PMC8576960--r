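#' Default two-class generative parameters for synthetic cohorts
#'
#' Describes the per-class distributions from which subject-level generative
#' parameters are drawn: Gaussian P-wave amplitude and width, mean RR, the
#' LF (0.1 Hz) and HF (0.25 Hz) oscillation amplitudes of the RR series, the
#' AR(1) noise scale, and the fraction of shuffled RR noise increments (a
#' nonlinearity knob that raises entropy and flattens short-range DFA
#' scaling). The PAF class has lower-amplitude, wider P-waves, reduced HF
#' (vagal) power with relatively increased LF power, reduced overall RR
#' variability, and more erratic beat-to-beat structure — the direction of
#' the differences reported for atrial-substrate remodelling.
#'
#' @param effect_scale Scales every PAF-vs-normal difference; `1` gives the
#'   frozen default cohort, `0` makes the classes identically distributed
#'   (a null cohort for permutation-style sanity checks).
#' @return A list with components `normal` and `PAF`, each a list of
#'   `mean`/`sd` pairs per generative parameter.
#' @export
default_class_params <- function(effect_scale = 1) {
  assert_scalar_num(effect_scale, "effect_scale")
  normal <- list(
    p_amp_mv     = c(mean = 0.15, sd = 0.015),  # Gaussian P amplitude A
    p_width_ms   = c(mean = 29,   sd = 2.5),    # Gaussian P width W (ms)
    mean_rr_ms   = c(mean = 800,  sd = 40),
    lf_amp_ms    = c(mean = 15,   sd = 3),
    hf_amp_ms    = c(mean = 20,   sd = 4),
    ar_sd_ms     = c(mean = 35,   sd = 5),
    shuffle_frac = c(mean = 0,    sd = 0)
  )
  paf <- list(
    p_amp_mv     = c(mean = 0.10, sd = 0.015),
    p_width_ms   = c(mean = 37,   sd = 2.5),
    mean_rr_ms   = c(mean = 780,  sd = 40),
    lf_amp_ms    = c(mean = 25,   sd = 3),
    hf_amp_ms    = c(mean = 8,    sd = 3),
    ar_sd_ms     = c(mean = 20,   sd = 5),
    shuffle_frac = c(mean = 0.4,  sd = 0.05)
  )
  for (nm in names(paf)) {
    paf[[nm]]["mean"] <- normal[[nm]]["mean"] +
      effect_scale * (paf[[nm]]["mean"] - normal[[nm]]["mean"])
    if (effect_scale == 0) paf[[nm]]["sd"] <- normal[[nm]]["sd"]
  }
  list(normal = normal, PAF = paf)
}

#' Specify a synthetic two-class ECG cohort
#'
#' The defaults emulate the study regime the package targets: single lead,
#' 128 Hz, 30-minute records with no AF episode, 50 PAF and 50 normal
#' subjects.
#'
#' @param n_per_class Subjects per class.
#' @param fs Sampling frequency in Hz.
#' @param duration Record duration in seconds.
#' @param seed Root seed; every record is reproducible from (spec, seed).
#' @param class_params Per-class generative distributions, see
#'   [default_class_params()].
#' @param noise_sd Additive white measurement noise, sd in mV.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 50, fs = 128, duration = 1800,
                        seed = 1, class_params = default_class_params(),
                        noise_sd = 0.01) {
  if (n_per_class < 1) stopf("'n_per_class' must be >= 1")
  assert_scalar_num(fs, "fs", positive = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  structure(list(n_per_class = n_per_class, fs = fs, duration = duration,
                 seed = seed, class_params = class_params,
                 noise_sd = noise_sd),
            class = "cohort_spec")
}

#' Generate a synthetic RR-interval series
#'
#' `RR[k] = mean_rr + lf_amp * sin(2*pi*0.1*t_k) + hf_amp * sin(2*pi*0.25*t_k)
#' + AR(1) noise`, with beat times accumulated from the intervals
#' themselves. A fraction `shuffle_frac` of the AR noise values is randomly
#' permuted, which preserves the marginal distribution while scrambling
#' short-range temporal correlation (raising entropy, pulling DFA alpha1
#' toward 0.5).
#'
#' @param n_beats Number of intervals to generate (>= 2).
#' @param mean_rr Mean RR in ms.
#' @param lf_amp,hf_amp Amplitudes (ms) of the 0.1 Hz and 0.25 Hz
#'   modulations.
#' @param ar_sd Marginal sd (ms) of the AR(1) noise component.
#' @param ar_coef AR(1) coefficient.
#' @param shuffle_frac Fraction of noise values to permute, in \[0, 1\].
#' @param seed Seed.
#' @return An [rr_series()].
#' @examples
#' synth_rr_series(5, mean_rr = 1000, lf_amp = 0, hf_amp = 0,
#'                 ar_sd = 0, seed = 1)$intervals  # constant 1000
#' @export
synth_rr_series <- function(n_beats, mean_rr = 800, lf_amp = 15,
                            hf_amp = 20, ar_sd = 30, ar_coef = 0.8,
                            shuffle_frac = 0, seed = 1) {
  if (n_beats < 2) stopf("'n_beats' must be >= 2")
  assert_scalar_num(mean_rr, "mean_rr", positive = TRUE)
  if (shuffle_frac < 0 || shuffle_frac > 1)
    stopf("'shuffle_frac' must be in [0, 1]")
  with_seed(seed, {
    innov_sd <- ar_sd * sqrt(1 - ar_coef^2)
    e <- as.numeric(stats::filter(stats::rnorm(n_beats, 0, innov_sd),
                                  ar_coef, method = "recursive"))
    if (ar_sd == 0) e <- numeric(n_beats)
    if (shuffle_frac > 0) {
      k <- floor(shuffle_frac * n_beats)
      if (k >= 2) {
        idx <- sort(sample.int(n_beats, k))
        e[idx] <- e[sample(idx)]
      }
    }
    rr <- numeric(n_beats)
    t <- 0
    for (k in seq_len(n_beats)) {
      rr[k] <- mean_rr + lf_amp * sin(2 * pi * 0.1 * t) +
        hf_amp * sin(2 * pi * 0.25 * t) + e[k]
      if (rr[k] <= 0)
        stopf("parameter error: generated RR interval <= 0 at beat %d", k)
      t <- t + rr[k] / 1000
    }
    rr_series(rr)
  })
}

# additive Gaussian bump on a sample-time grid (times and center in ms)
gauss_bump <- function(t_ms, center_ms, amp, width_ms) {
  amp * exp(-((t_ms - center_ms) / width_ms)^2)
}

#' Render one synthetic heartbeat
#'
#' P, QRS and T waves are rendered as parameterized bumps on a grid of
#' `round(rr_ms / 1000 * fs)` samples; the P-wave is an exact Gaussian
#' `A * exp(-((t - C)/W)^2)` so the fitting stage has known ground truth.
#' The R peak sits at `r_at_ms` from beat onset, the P center `pr_ms`
#' before it and the T wave `rt_ms` after it.
#'
#' @param fs Sampling frequency (Hz).
#' @param rr_ms Beat length in ms.
#' @param p_amp,p_width_ms Gaussian P amplitude (mV) and width (ms).
#' @param pr_ms P-center-to-R-peak time (ms).
#' @param r_at_ms R-peak offset from beat onset (ms).
#' @param r_amp,t_amp Peak amplitudes (mV) of the R and T waves.
#' @param rt_ms R-to-T-center time (ms).
#' @return A list with `samples`, and the ground-truth `r_peak` (sample
#'   index) and P-wave `(A, C, W)` in sample units (`p_center`,
#'   `p_width_samples`).
#' @export
synth_beat <- function(fs, rr_ms = 800, p_amp = 0.15, p_width_ms = 29,
                       pr_ms = 160, r_at_ms = 300, r_amp = 1,
                       t_amp = 0.2, rt_ms = 280) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  # supports (where the bump exceeds ~5% of its peak) must not collide
  half_p <- p_width_ms * sqrt(log(20))
  if (pr_ms - half_p < 40)
    stopf("parameter error: P-wave support overlaps the QRS complex")
  if (rt_ms - 40 < 1.2 * 50)
    stopf("parameter error: T-wave support overlaps the QRS complex")
  n <- round(rr_ms / 1000 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  y <- gauss_bump(t_ms, r_at_ms - pr_ms, p_amp, p_width_ms) +      # P
    gauss_bump(t_ms, r_at_ms, r_amp, 10) +                         # R
    gauss_bump(t_ms, r_at_ms - 28, -0.15 * r_amp, 6) +             # Q
    gauss_bump(t_ms, r_at_ms + 28, -0.25 * r_amp, 6) +             # S
    gauss_bump(t_ms, r_at_ms + rt_ms, t_amp, 50)                   # T
  list(samples = y,
       r_peak = round(r_at_ms / 1000 * fs) + 1L,
       p_center = (r_at_ms - pr_ms) / 1000 * fs + 1,
       p_amp = p_amp,
       p_width_samples = p_width_ms / 1000 * fs)
}

#' Generate one synthetic ECG record with ground truth
#'
#' Lays beats from a [synth_rr_series()] onto a continuous sample grid,
#' rendering each beat's P-wave as an exact Gaussian, then adds white
#' measurement noise. Ground truth (R-peak indices, per-beat P-wave
#' `(A, C, W)`, the RR series, and all generative parameters) is attached
#' as the `"truth"` attribute for parameter-recovery testing.
#'
#' @param subject_id,label Record identity; `label` in `{PAF, normal}`.
#' @param fs,duration Sampling rate (Hz) and duration (s).
#' @param params Named list of subject-level generative parameters
#'   (`p_amp_mv`, `p_width_ms`, `mean_rr_ms`, `lf_amp_ms`, `hf_amp_ms`,
#'   `ar_sd_ms`, `shuffle_frac`).
#' @param noise_sd Additive white noise sd in mV.
#' @param seed Seed.
#' @return An [ecg_record()] carrying a `"truth"` attribute.
#' @export
synth_record <- function(subject_id, label = NA_character_, fs = 128,
                         duration = 1800,
                         params = list(p_amp_mv = 0.15, p_width_ms = 29,
                                       mean_rr_ms = 800, lf_amp_ms = 15,
                                       hf_amp_ms = 20, ar_sd_ms = 35,
                                       shuffle_frac = 0),
                         noise_sd = 0.01, seed = 1) {
  n_beats <- ceiling(duration * 1000 / params$mean_rr_ms * 1.3) + 5
  rr <- synth_rr_series(n_beats, mean_rr = params$mean_rr_ms,
                        lf_amp = params$lf_amp_ms,
                        hf_amp = params$hf_amp_ms,
                        ar_sd = params$ar_sd_ms,
                        shuffle_frac = params$shuffle_frac,
                        seed = derive_seed(seed, 1))
  r_times <- 0.5 + rr$beat_times                       # first R at 0.5 s
  keep <- r_times < duration - 0.5
  r_times <- r_times[keep]
  n <- round(duration * fs)
  y <- numeric(n)
  pr_ms <- 160
  # one vectorized pass per wave type: bumps of the same type never
  # overlap across beats, so scatter-add by flat indexing is safe
  add_bumps <- function(y, centers_ms, amp, width_ms) {
    half <- 5 * width_ms
    len <- ceiling(2 * half / 1000 * fs) + 1L
    i0 <- floor((centers_ms - half) / 1000 * fs) + 1L
    idx <- outer(i0, 0:(len - 1L), "+")
    ok <- idx >= 1L & idx <= n
    t_ms <- (idx - 1) / fs * 1000
    val <- gauss_bump(t_ms, centers_ms, amp, width_ms)
    y[idx[ok]] <- y[idx[ok]] + val[ok]
    y
  }
  tr <- r_times * 1000
  y <- add_bumps(y, tr - pr_ms, params$p_amp_mv, params$p_width_ms)
  y <- add_bumps(y, tr, 1, 10)
  y <- add_bumps(y, tr - 28, -0.15, 6)
  y <- add_bumps(y, tr + 28, -0.25, 6)
  y <- add_bumps(y, tr + 280, 0.2, 50)
  if (noise_sd > 0)
    y <- y + with_seed(derive_seed(seed, 2), stats::rnorm(n, 0, noise_sd))
  rec <- ecg_record(y, fs = fs, subject_id = subject_id, label = label)
  attr(rec, "truth") <- list(
    r_peaks = round(r_times * fs) + 1L,
    p_centers = (r_times * 1000 - pr_ms) / 1000 * fs + 1,
    p_amp = params$p_amp_mv,
    p_width_samples = params$p_width_ms / 1000 * fs,
    pw_ms = 2 * sqrt(log(20)) * params$p_width_ms,
    rr = rr_series(diff(r_times) * 1000, beat_times = r_times),
    params = params, seed = seed)
  rec
}

#' Generate a labeled two-class synthetic cohort
#'
#' Draws subject-level generative parameters from the per-class
#' distributions in the spec and renders one ECG record per subject. With
#' the frozen defaults this emulates a 50 + 50, 30-minute, 128 Hz cohort
#' whose classes differ in P-wave morphology, spectral balance and
#' beat-to-beat regularity.
#'
#' @param spec A [cohort_spec()].
#' @param progress Print one line per record.
#' @return A list of [ecg_record()]s (classes interleaved normal/PAF), each
#'   carrying its generating ground truth.
#' @export
synth_cohort <- function(spec = cohort_spec(), progress = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  records <- vector("list", 2L * spec$n_per_class)
  k <- 0L
  for (i in seq_len(spec$n_per_class)) {
    for (cls in c("normal", "PAF")) {
      k <- k + 1L
      sid <- sprintf("%s%03d", if (cls == "PAF") "p" else "n", i)
      pars <- draw_subject_params(spec$class_params[[cls]],
                                  derive_seed(spec$seed, k))
      records[[k]] <- synth_record(sid, label = cls, fs = spec$fs,
                                   duration = spec$duration, params = pars,
                                   noise_sd = spec$noise_sd,
                                   seed = derive_seed(spec$seed, 1000L + k))
      if (progress)
        message(sprintf("generated %s (%s)", sid, cls))
    }
  }
  records
}

draw_subject_params <- function(class_dist, seed) {
  with_seed(seed, {
    pars <- lapply(class_dist, function(p)
      stats::rnorm(1, p[["mean"]], p[["sd"]]))
    # keep draws physiological
    pars$p_amp_mv <- max(pars$p_amp_mv, 0.04)
    pars$p_width_ms <- max(pars$p_width_ms, 10)
    pars$mean_rr_ms <- max(pars$mean_rr_ms, 450)
    pars$ar_sd_ms <- max(pars$ar_sd_ms, 0)
    pars$shuffle_frac <- min(max(pars$shuffle_frac, 0), 1)
    pars
  })
}
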