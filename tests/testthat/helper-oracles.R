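# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's code paths: sort-based order statistics, explicit
# sums-of-squares ANOVA, explicit binomial tail sums.

# Per-index window scan with sort-based median/min; centered window of w
# samples (odd), shrinking at the edges; NA ignored, all-NA window -> NA.
brute_window_stat <- function(x, w, which = c("median", "min")) {
  which <- match.arg(which)
  n <- length(x)
  half <- (w - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- x[max(1, i - half):min(n, i + half)]
    v <- sort(win[!is.na(win)])          # sort() drops nothing else
    m <- length(v)
    if (m == 0) next
    out[i] <- if (which == "min") {
      v[1]
    } else if (m %% 2 == 1) {
      v[(m + 1) / 2]
    } else {
      (v[m / 2] + v[m / 2 + 1]) / 2
    }
  }
  out
}

# ICC(A,1) point estimate from explicit sums of squares.
oracle_icc_a1 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - gm)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - gm)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + gm)^2
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# One-sided upper binomial tail P(X >= x) by explicit enumeration.
oracle_binom_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  sum(vapply(x:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
             numeric(1)))
}

# A clean noise-free test signal with k cycles and its spec.
clean_signal <- function(k = 5, period = 5, seed = 1, noise_sd_cm = 0, ...) {
  generate_signal(synthetic_spec(n_cycles = k, period_s = period,
                                 noise_sd_cm = noise_sd_cm, seed = seed, ...))
}

# Older-regime spike batch used by the degradation/contrast properties:
# abundant clustered bursts whose heights straddle the 99-cm ceiling.
spike_batch_spec <- function(seed) {
  synthetic_spec(n_cycles = 9, period_s = 3, rise_s = 1, noise_sd_cm = 1,
                 spike_rate_per_s = 0.5, spike_cluster_size = 4,
                 spike_height_cm = c(40, 110), seed = seed)
}
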