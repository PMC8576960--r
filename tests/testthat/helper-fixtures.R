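# Shared fixtures built in code.

# short noiseless-ish record with known beat structure
make_clean_record <- function(duration = 60, seed = 101, noise_sd = 0,
                              params = list(p_amp_mv = 0.15, p_width_ms = 29,
                                            mean_rr_ms = 1000, lf_amp_ms = 0,
                                            hf_amp_ms = 0, ar_sd_ms = 0,
                                            shuffle_frac = 0)) {
  synth_record("clean", label = "normal", duration = duration,
               params = params, noise_sd = noise_sd, seed = seed)
}

# small separable two-class feature set for ensemble tests
make_toy_features <- function(n_per_class = 20, seed = 7, shift = 3) {
  set.seed(seed)
  data.frame(
    x1 = c(rnorm(n_per_class, 0), rnorm(n_per_class, shift)),
    x2 = rnorm(2 * n_per_class),
    label = rep(c("normal", "PAF"), each = n_per_class)
  )
}

# naive brute-force oracles -------------------------------------------

bf_sd <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1))

bf_rmssd <- function(x) {
  d <- x[-1] - x[-length(x)]
  sqrt(sum(d^2) / length(d))
}

bf_apen <- function(u, m, r) {
  N <- length(u)
  phi <- function(mm) {
    L <- N - mm + 1
    cnt <- numeric(L)
    for (i in 1:L) for (j in 1:L) {
      if (max(abs(u[i:(i + mm - 1)] - u[j:(j + mm - 1)])) <= r)
        cnt[i] <- cnt[i] + 1
    }
    mean(log(cnt / L))
  }
  phi(m) - phi(m + 1)
}

bf_sampen <- function(u, m, r) {
  N <- length(u)
  count <- function(mm) {
    L <- N - m
    tot <- 0
    for (i in 1:(L - 1)) for (j in (i + 1):L) {
      if (max(abs(u[i:(i + mm - 1)] - u[j:(j + mm - 1)])) <= r)
        tot <- tot + 1
    }
    tot
  }
  B <- count(m); A <- count(m + 1)
  -log(A / B)
}

bf_auroc <- function(scores, labels) {
  pos <- which(labels == "PAF"); neg <- which(labels == "normal")
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1
    else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
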