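#' Time-domain heart-rate-variability parameters
#'
#' Computes the 11 time-domain HRV parameters from an RR-interval series:
#' mean RR and SDNN (sample sd), mean/sd of instantaneous heart rate
#' (`HR = 60000 / RR`), minimum and maximum per-minute mean heart rate,
#' RMSSD, NN50 and pNN50, and the two geometric measures from the RR
#' histogram (HRV triangular index and TINN).
#'
#' Details of the geometric measures: the histogram uses a fixed bin
#' width (default 7.8125 ms, i.e. 1/128 s); the triangular index is the
#' total interval count divided by the height of the histogram mode;
#' TINN is the base width `N - M` of the triangle with apex fixed at the
#' mode (position and height) that minimizes the squared error against
#' the histogram, found by exhaustive search over bin-edge pairs with
#' ties broken toward the narrower base.
#'
#' @param rr An [rr_series()] with at least 2 intervals.
#' @param binwidth_ms Histogram bin width in ms.
#' @param pnn50_denominator `"diffs"` (number of successive-difference
#'   pairs, N-1; the default) or `"intervals"` (N).
#' @return A list of class `hrv_time` with elements `RRmean`, `SDNN`,
#'   `HRmean`, `SDHR`, `MinHR`, `MaxHR`, `RMSSD`, `NN50`, `pNN50`,
#'   `HRVTriangularIndex`, `TINN`.
#' @examples
#' time_domain_features(rr_series(rep(800, 10)))$HRmean  # 75 bpm
#' @export
time_domain_features <- function(rr, binwidth_ms = 7.8125,
                                 pnn50_denominator = c("diffs", "intervals")) {
  stopifnot(inherits(rr, "rr_series"))
  pnn50_denominator <- match.arg(pnn50_denominator)
  x <- rr$intervals
  n <- length(x)
  if (n < 2L)
    stopf("insufficient data: need at least 2 RR intervals")
  hr <- 60000 / x
  d <- diff(x)
  nn50 <- sum(abs(d) > 50)
  denom <- if (pnn50_denominator == "diffs") length(d) else n
  # per-minute windowed mean HR; short records fall back to beat-wise HR
  bt <- if (length(rr$beat_times) == n + 1L) rr$beat_times[-1L] else rr$beat_times
  span <- bt[n] - bt[1L]
  if (span >= 60) {
    bins <- floor((bt - bt[1L]) / 60)
    whr <- tapply(hr, bins, mean)
  } else {
    whr <- hr
  }
  geom <- rr_histogram_geometry(x, binwidth_ms)
  structure(list(
    RRmean = mean(x),
    SDNN = stats::sd(x),
    HRmean = mean(hr),
    SDHR = stats::sd(hr),
    MinHR = min(whr),
    MaxHR = max(whr),
    RMSSD = sqrt(mean(d^2)),
    NN50 = nn50,
    pNN50 = 100 * nn50 / denom,
    HRVTriangularIndex = geom$tri_index,
    TINN = geom$tinn
  ), class = "hrv_time")
}

# RR histogram on a fixed-width grid; triangular index and TINN by
# exhaustive triangle-base search with the apex pinned at the mode.
rr_histogram_geometry <- function(x, bw) {
  lo <- floor(min(x) / bw) * bw
  hi <- ceiling(max(x) / bw) * bw
  if (hi <= lo) hi <- lo + bw
  edges <- seq(lo, hi, by = bw)
  counts <- tabulate(pmin(findInterval(x, edges), length(edges) - 1L),
                     nbins = length(edges) - 1L)
  H <- max(counts)
  mode_bin <- which.max(counts)
  mids <- edges[-length(edges)] + bw / 2
  apex <- mids[mode_bin]
  cand_M <- edges[edges <= apex - bw / 2]
  cand_N <- edges[edges >= apex + bw / 2]
  best <- Inf; best_w <- Inf; tinn <- 0
  for (M in cand_M) for (N in cand_N) {
    tri <- numeric(length(mids))
    left <- mids >= M & mids <= apex
    right <- mids > apex & mids <= N
    if (apex > M) tri[left] <- H * (mids[left] - M) / (apex - M)
    if (N > apex) tri[right] <- H * (N - mids[right]) / (N - apex)
    err <- sum((counts - tri)^2)
    w <- N - M
    if (err < best - 1e-12 || (abs(err - best) <= 1e-12 && w < best_w)) {
      best <- err; best_w <- w; tinn <- w
    }
  }
  list(tri_index = length(x) / H, tinn = tinn)
}
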