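#' Poincare-plot dispersion of an RR series
#'
#' From consecutive interval pairs `(RR[n], RR[n+1])`:
#' `SD1 = sd((RR[n] - RR[n+1]) / sqrt(2))` (dispersion perpendicular to
#' the identity line, short-term variability) and
#' `SD2 = sd((RR[n] + RR[n+1]) / sqrt(2))` (dispersion along it,
#' long-term variability), with the sample (n-1) sd convention.
#'
#' @param rr An [rr_series()] with at least 3 intervals.
#' @return List with `SD1`, `SD2` (ms) and `SD2_SD1` (`NA` when SD1 is 0).
#' @export
poincare_sd <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  n <- length(x)
  if (n < 3L)
    stopf("insufficient data: need at least 3 RR intervals")
  x1 <- x[-n]; x2 <- x[-1L]
  sd1 <- stats::sd((x1 - x2) / sqrt(2))
  sd2 <- stats::sd((x1 + x2) / sqrt(2))
  list(SD1 = sd1, SD2 = sd2,
       SD2_SD1 = if (sd1 > 0) sd2 / sd1 else NA_real_)
}

# Chebyshev-distance template-match matrix for embedding dimension m,
# over templates starting at 1..L (L rows/cols)
cheb_match <- function(D, m, L) {
  M <- D[seq_len(L), seq_len(L), drop = FALSE]
  if (m > 1L)
    for (k in seq_len(m - 1L))
      M <- pmax(M, D[k + seq_len(L), k + seq_len(L), drop = FALSE])
  M
}

#' Approximate entropy (Pincus)
#'
#' `ApEn = Phi_m(r) - Phi_{m+1}(r)` where
#' `Phi_m = mean_i log(C_i^m)` and `C_i^m` is the self-match-inclusive
#' fraction of templates of length `m` within Chebyshev distance `r` of
#' template `i`. Larger values mean a more irregular series.
#'
#' @param series Numeric series of length `>= m + 2`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance in the series' own units; must be positive.
#' @return Approximate entropy (dimensionless, `>= 0`).
#' @export
apen <- function(series, m = 2, r) {
  series <- as.numeric(series)
  N <- length(series)
  if (r <= 0) stopf("domain error: tolerance r must be positive")
  if (N < m + 2) stopf("insufficient data: need length >= m + 2")
  D <- abs(outer(series, series, "-"))
  phi <- function(mm) {
    L <- N - mm + 1L
    M <- cheb_match(D, mm, L)
    mean(log(rowSums(M <= r) / L))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy (Richman–Moorman)
#'
#' `SampEn = -log(A / B)` where `B` counts template pairs of length `m`
#' and `A` pairs of length `m + 1` within Chebyshev distance `r`,
#' self-matches excluded, with the same `N - m` templates for both
#' lengths.
#'
#' @inheritParams apen
#' @return Sample entropy, or `NA` when no matches exist at either
#'   length (undefined).
#' @export
sampen <- function(series, m = 2, r) {
  series <- as.numeric(series)
  N <- length(series)
  if (r <= 0) stopf("domain error: tolerance r must be positive")
  if (N < m + 2) stopf("insufficient data: need length >= m + 2")
  D <- abs(outer(series, series, "-"))
  L <- N - m
  B <- (sum(cheb_match(D, m, L) <= r) - L) / 2
  A <- (sum(cheb_match(D, m + 1L, L) <= r) - L) / 2
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# ApEn and SampEn in one pass, sharing the pairwise distance matrices;
# numerically identical to apen() and sampen()
apen_sampen <- function(series, m, r) {
  x <- as.numeric(series)
  N <- length(x)
  D <- abs(outer(x, x, "-"))
  L1 <- N - m + 1L
  Mm <- cheb_match(D, m, L1)
  phi_m <- mean(log(rowSums(Mm <= r) / L1))
  L2 <- N - m
  S <- Mm[seq_len(L2), seq_len(L2), drop = FALSE]
  B <- (sum(S <= r) - L2) / 2
  Mm1 <- pmax(S, D[m + seq_len(L2), m + seq_len(L2), drop = FALSE])
  A <- (sum(Mm1 <= r) - L2) / 2
  # phi_{m+1} over the N - m templates, self-match-inclusive
  phi_m1 <- mean(log(rowSums(Mm1 <= r) / L2))
  list(ApEn = phi_m - phi_m1,
       SampEn = if (A == 0 || B == 0) NA_real_ else -log(A / B))
}

# Exact expected fluctuation of linearly detrended integrated white
# noise (unit variance) in a box of length n: ||(I - H) C||_F / sqrt(n),
# with C the cumulative-sum operator and H the hat matrix of a line fit.
# Used to remove the small-box finite-size bias of first-order DFA.
dfa_white_expectation <- function(n) {
  C <- matrix(0, n, n)
  C[lower.tri(C, diag = TRUE)] <- 1
  X <- cbind(1, seq_len(n))
  H <- X %*% solve(crossprod(X), t(X))
  M <- (diag(n) - H) %*% C
  sqrt(sum(M^2) / n)
}

#' Detrended fluctuation analysis scaling exponents
#'
#' The mean-centered series is integrated; for each box size `n` the
#' profile is split into non-overlapping boxes, each detrended by a
#' least-squares line, and the fluctuation `F(n)` is the rms residual.
#' `alpha1` and `alpha2` are the least-squares slopes of `log F(n)`
#' versus `log n` over the short- and long-range box sizes.
#'
#' At the small box sizes of the short range, raw first-order DFA has a
#' known finite-size bias (the expected fluctuation of even uncorrelated
#' noise does not follow the asymptotic `sqrt(n/15)` law at `n` near 4,
#' inflating the short-range slope). By default the fluctuations are
#' rescaled by the exact white-noise expectation, computed from the
#' detrending operator, so that uncorrelated input has expected slope
#' 0.5 at every box size; the correction factor tends to 1 as `n`
#' grows.
#'
#' @param series Numeric series with `length >= 4 * max(box sizes)`.
#' @param short_range,long_range Integer box-size vectors (defaults
#'   4–16 and 16–64 beats, the HRV convention).
#' @param bias_correction Apply the exact white-noise finite-size
#'   rescaling (default `TRUE`).
#' @return List with `alpha1`, `alpha2`, and the per-size fluctuations
#'   (`n`, `F`).
#' @export
dfa <- function(series, short_range = 4:16, long_range = 16:64,
                bias_correction = TRUE) {
  series <- as.numeric(series)
  N <- length(series)
  sizes <- sort(unique(c(short_range, long_range)))
  if (N < 4 * max(short_range))
    stopf("insufficient data: need length >= 4 * max short-range box size")
  sizes <- sizes[sizes * 4 <= N]
  y <- cumsum(series - mean(series))
  Fn <- vapply(sizes, function(n) {
    K <- N %/% n
    Y <- matrix(y[seq_len(K * n)], nrow = n)
    t <- seq_len(n)
    tc <- t - mean(t)
    beta <- colSums(Y * tc) / sum(tc^2)
    res <- sweep(Y, 2L, colMeans(Y)) - outer(tc, beta)
    sqrt(mean(res^2))
  }, numeric(1))
  if (bias_correction) {
    w <- vapply(sizes, dfa_white_expectation, numeric(1))
    Fn <- Fn / w * sqrt(sizes / 15)
  }
  slope <- function(range) {
    ok <- sizes %in% range & Fn > 0
    if (sum(ok) < 2L) return(NA_real_)
    stats::coef(stats::lm.fit(cbind(1, log(sizes[ok])),
                              log(Fn[ok])))[2L]
  }
  list(alpha1 = unname(slope(short_range)),
       alpha2 = unname(slope(long_range)),
       n = sizes, F = Fn)
}

#' Nonlinear HRV parameters from an RR series
#'
#' Poincare SD1/SD2 and their ratio, approximate and sample entropy
#' (`m = 2`, `r = r_factor * SDNN` of the series, the HRV convention),
#' and DFA `alpha1`/`alpha2`.
#'
#' @param rr An [rr_series()].
#' @param m Embedding dimension for the entropies.
#' @param r_factor Entropy tolerance as a fraction of the series sd.
#' @param short_range,long_range DFA box-size ranges (beats).
#' @return A list of class `hrv_nonlinear` with `SD1`, `SD2`, `SD2_SD1`,
#'   `ApEn`, `SampEn`, `alpha1`, `alpha2`.
#' @export
nonlinear_features <- function(rr, m = 2, r_factor = 0.2,
                               short_range = 4:16, long_range = 16:64) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  pc <- poincare_sd(rr)
  r <- max(r_factor * stats::sd(x), 1e-9)
  ent <- if (length(x) >= m + 2) apen_sampen(x, m, r)
  else list(ApEn = NA_real_, SampEn = NA_real_)
  ae <- ent$ApEn
  se <- ent$SampEn
  al <- if (length(x) >= 4 * max(short_range))
    dfa(x, short_range, long_range)
  else list(alpha1 = NA_real_, alpha2 = NA_real_)
  structure(list(SD1 = pc$SD1, SD2 = pc$SD2, SD2_SD1 = pc$SD2_SD1,
                 ApEn = ae, SampEn = se,
                 alpha1 = al$alpha1, alpha2 = al$alpha2),
            class = "hrv_nonlinear")
}
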