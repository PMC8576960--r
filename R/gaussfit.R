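#' Evaluate the Gaussian P-wave model
#'
#' The P-wave is modelled as `y(i) = A * exp(-((i - C) / W)^2)` over the
#' segment's own 1-based sample coordinates `i = 1, ..., D`; `A` is the
#' amplitude, `C` the center and `W` the width.
#'
#' @param params Numeric `c(A, C, W)` (names optional).
#' @param i Evaluation point(s), real-valued.
#' @return `A * exp(-((i - C)/W)^2)`.
#' @examples
#' gaussian_eval(c(2, 5, 3), 5)      # 2 at the center
#' gaussian_eval(c(1, 0, 1), 1)      # exp(-1)
#' @export
gaussian_eval <- function(params, i) {
  params <- as.numeric(params)
  if (length(params) != 3L || !all(is.finite(params)))
    stopf("'params' must be finite c(A, C, W)")
  if (params[3L] <= 0)
    stopf("domain error: width W must be positive")
  params[1L] * exp(-((i - params[2L]) / params[3L])^2)
}

#' Sum-of-squares fitting error of a Gaussian against a P-wave segment
#'
#' @param params Numeric `c(A, C, W)`.
#' @param segment Baseline-subtracted P-wave samples (length `D >= 4`
#'   for fitting; any length `>= 1` for evaluation).
#' @return `sum((segment[i] - y(i))^2)` over `i = 1..D`.
#' @export
fit_sse <- function(params, segment) {
  segment <- as.numeric(segment)
  sum((segment - gaussian_eval(params, seq_along(segment)))^2)
}

# SSE of many (A, C, W) rows against one segment, vectorized over rows;
# seq_len(D) recycles down each column of the D x P residual matrix
sse_pop <- function(pop, segment) {
  D <- length(segment)
  P <- nrow(pop)
  A <- rep(pop[, 1L], each = D)
  C <- rep(pop[, 2L], each = D)
  W <- rep(pop[, 3L], each = D)
  r <- segment - A * exp(-((seq_len(D) - C) / W)^2)
  .colSums(r * r, D, P)
}

# L4(2^3) orthogonal array: rows = runs, columns = the 3 factors A, C, W
L4 <- matrix(c(1, 1, 1,
               1, 2, 2,
               2, 1, 2,
               2, 2, 1), nrow = 4, byrow = TRUE)

#' Taguchi orthogonal-array crossover for the Gaussian fit
#'
#' The two-level L4(2^3) orthogonal array is laid over the three factors
#' (A, C, W), with level 1 = `parent1`'s value and level 2 = `parent2`'s.
#' Each array run's SSE against the segment is turned into a
#' signal-to-noise ratio `eta = -10 * log10(SSE + eps)`; for each factor
#' the level with the larger mean SNR is kept, and the assembled child is
#' returned.
#'
#' @param parent1,parent2 Numeric `c(A, C, W)`.
#' @param segment Baseline-subtracted P-wave samples.
#' @param eps Guard added inside the log at perfect fits.
#' @return The child `c(A, C, W)`.
#' @export
taguchi_crossover <- function(parent1, parent2, segment, eps = 1e-12) {
  P <- rbind(as.numeric(parent1), as.numeric(parent2))
  runs <- matrix(0, nrow = 4L, ncol = 3L)
  for (f in 1:3) runs[, f] <- P[L4[, f], f]
  eta <- -10 * log10(sse_pop(runs, segment) + eps)
  child <- numeric(3L)
  for (f in 1:3) {
    m1 <- mean(eta[L4[, f] == 1L])
    m2 <- mean(eta[L4[, f] == 2L])
    child[f] <- if (m1 >= m2) P[1L, f] else P[2L, f]
  }
  child
}

#' Configuration for the hybrid Taguchi-genetic Gaussian fit
#'
#' @param population_size Even integer `>= 4`.
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate Probabilities in `[0, 1]`.
#' @param mutation_scale Initial per-gene Gaussian perturbation sd as a
#'   fraction of the parameter range.
#' @param anneal Per-generation multiplicative decay of the mutation
#'   scale (geometric annealing toward fine local refinement).
#' @param bounds Optional 3 x 2 matrix of `(low, high)` per parameter
#'   (rows A, C, W); defaults are derived from the segment.
#' @param seed Seed; the fit is deterministic given the seed.
#' @return A list of class `htga_config`.
#' @export
htga_config <- function(population_size = 50, generations = 100,
                        crossover_rate = 0.8, mutation_rate = 0.1,
                        mutation_scale = 0.1, anneal = 0.95,
                        bounds = NULL, seed = 1) {
  if (population_size < 4 || population_size %% 2 != 0)
    stopf("configuration error: population_size must be even and >= 4")
  if (generations < 1)
    stopf("configuration error: generations must be >= 1")
  for (r in c(crossover_rate, mutation_rate))
    if (r < 0 || r > 1)
      stopf("configuration error: rates must be in [0, 1]")
  if (!is.null(bounds)) {
    bounds <- matrix(as.numeric(bounds), nrow = 3L)
    if (any(bounds[, 1L] >= bounds[, 2L]))
      stopf("configuration error: each bound must satisfy low < high")
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_scale = mutation_scale,
                 anneal = anneal, bounds = bounds, seed = seed),
            class = "htga_config")
}

#' Fit the Gaussian P-wave model by the hybrid Taguchi-genetic algorithm
#'
#' Generational GA with size-2 tournament selection, Taguchi
#' orthogonal-array crossover ([taguchi_crossover()]), annealed per-gene
#' Gaussian-perturbation mutation clipped to the bounds, and elitism that
#' re-inserts the incumbent best each generation, so the best-ever SSE is
#' non-increasing. Default bounds: `A` in `[0, 2 * max(|segment|)]`, `C`
#' in `[1, D]`, `W` in `[0.5, D]`.
#'
#' @param segment Baseline-subtracted P-wave samples, `D >= 4`.
#' @param config An [htga_config()].
#' @return An object of class `htga_fit`: list with `par` (named
#'   `c(A, C, W)`), `sse`, `trace` (best-ever SSE per generation), and
#'   the config used.
#' @examples
#' seg <- gaussian_eval(c(0.2, 12, 4), 1:24)
#' fit <- htga_fit(seg, htga_config(seed = 7))
#' coef(fit)
#' @export
htga_fit <- function(segment, config = htga_config()) {
  segment <- as.numeric(segment)
  D <- length(segment)
  if (D < 4L)
    stopf("insufficient data: P-wave segment must have >= 4 samples")
  if (!all(is.finite(segment)))
    stopf("segment must be finite")
  stopifnot(inherits(config, "htga_config"))
  b <- config$bounds %||% rbind(A = c(0, 2 * max(abs(segment), 1e-6)),
                                C = c(1, D),
                                W = c(0.5, D))
  lo <- b[, 1L]; hi <- b[, 2L]; rng <- hi - lo
  P <- config$population_size
  with_seed(config$seed, {
    pop <- cbind(stats::runif(P, lo[1], hi[1]),
                 stats::runif(P, lo[2], hi[2]),
                 stats::runif(P, lo[3], hi[3]))
    best_par <- NULL
    best_sse <- Inf
    trace <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      sse <- sse_pop(pop, segment)
      ib <- which.min(sse)
      if (sse[ib] < best_sse) {
        best_sse <- sse[ib]
        best_par <- pop[ib, ]
      }
      trace[g] <- best_sse
      # size-2 tournament selection
      i1 <- sample.int(P, P, replace = TRUE)
      i2 <- sample.int(P, P, replace = TRUE)
      sel <- ifelse(sse[i1] <= sse[i2], i1, i2)
      pool <- pop[sel, , drop = FALSE]
      pool_sse <- sse[sel]
      # Taguchi crossover on consecutive pairs
      npair <- P %/% 2L
      cross <- stats::runif(npair) < config$crossover_rate
      newpop <- pool
      if (any(cross)) {
        jj <- which(cross)
        nc <- length(jj)
        P1 <- pool[2L * jj - 1L, , drop = FALSE]
        P2 <- pool[2L * jj, , drop = FALSE]
        # all L4 runs of all crossing pairs, evaluated in one batch
        runs <- matrix(0, nrow = 4L * nc, ncol = 3L)
        for (f in 1:3) {
          lev1 <- rep(L4[, f] == 1L, nc)
          runs[, f] <- ifelse(lev1, rep(P1[, f], each = 4L),
                              rep(P2[, f], each = 4L))
        }
        eta <- matrix(-10 * log10(sse_pop(runs, segment) + 1e-12), 4L)
        child <- matrix(0, nc, 3L)
        for (f in 1:3) {
          lev1 <- L4[, f] == 1L
          d <- .colSums(eta[lev1, , drop = FALSE], 2L, nc) -
            .colSums(eta[!lev1, , drop = FALSE], 2L, nc)
          child[, f] <- ifelse(d >= 0, P1[, f], P2[, f])
        }
        p1_better <- pool_sse[2L * jj - 1L] <= pool_sse[2L * jj]
        keep <- P2
        keep[p1_better, ] <- P1[p1_better, ]
        newpop[2L * jj - 1L, ] <- child
        newpop[2L * jj, ] <- keep
      }
      # annealed Gaussian mutation, clipped to bounds
      sd_g <- config$mutation_scale * config$anneal^(g - 1)
      mask <- matrix(stats::runif(P * 3L) < config$mutation_rate, P, 3L)
      if (any(mask)) {
        pert <- matrix(stats::rnorm(P * 3L, 0, 1), P, 3L) *
          matrix(rng * sd_g, P, 3L, byrow = TRUE)
        newpop[mask] <- newpop[mask] + pert[mask]
        newpop <- pmin(pmax(newpop, matrix(lo, P, 3L, byrow = TRUE)),
                       matrix(hi, P, 3L, byrow = TRUE))
      }
      # elitism: incumbent best survives
      newpop[1L, ] <- best_par
      pop <- newpop
    }
    sse <- sse_pop(pop, segment)
    ib <- which.min(sse)
    if (sse[ib] < best_sse) {
      best_sse <- sse[ib]
      best_par <- pop[ib, ]
    }
    structure(list(par = stats::setNames(best_par, c("A", "C", "W")),
                   sse = best_sse, trace = trace, D = D, config = config),
              class = "htga_fit")
  })
}

#' @export
print.htga_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian P-wave fit (HTGA): A = %.4g, C = %.4g, W = %.4g, SSE = %.4g (D = %d)\n",
    x$par["A"], x$par["C"], x$par["W"], x$sse, x$D))
  invisible(x)
}

#' @export
coef.htga_fit <- function(object, ...) object$par

#' Subject-level Gaussian P-wave parameters
#'
#' Fits the Gaussian model to each retained beat's baseline-subtracted
#' onset-to-offset segment with [htga_fit()] (on at most `max_beats`
#' evenly spaced beats) and aggregates `A`, `C`, `W` by the median, the
#' same policy as the direct P-wave parameters.
#'
#' @param record An [ecg_record()].
#' @param fiducials A [fiducial_set()] with per-beat baselines.
#' @param config An [htga_config()]; per-beat seeds are derived from its
#'   seed.
#' @param max_beats Cap on the number of beats fitted.
#' @return List of class `pwave_gauss` with `A`, `C`, `W` and a
#'   `per_beat` data frame (beat, A, C, W, SSE).
#' @export
gaussfit_features <- function(record, fiducials, config = htga_config(),
                              max_beats = 20) {
  stopifnot(inherits(record, "ecg_record"), inherits(fiducials, "fiducial_set"))
  nb <- length(fiducials$r_peaks)
  if (nb == 0L)
    stopf("insufficient data: empty fiducial set")
  use <- if (nb > max_beats)
    unique(round(seq(1L, nb, length.out = max_beats))) else seq_len(nb)
  x <- record$samples
  res <- lapply(use, function(k) {
    seg <- x[fiducials$p_onset[k]:fiducials$p_offset[k]]
    if (!is.null(fiducials$baseline)) seg <- seg - fiducials$baseline[k]
    if (length(seg) < 4L) return(NULL)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, k)
    cfg$bounds <- NULL
    fit <- htga_fit(seg, cfg)
    c(beat = k, fit$par, SSE = fit$sse)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L)
    stopf("insufficient data: no beat segment long enough to fit")
  per_beat <- as.data.frame(res)
  structure(list(A = stats::median(per_beat$A),
                 C = stats::median(per_beat$C),
                 W = stats::median(per_beat$W),
                 per_beat = per_beat),
            class = "pwave_gauss")
}
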