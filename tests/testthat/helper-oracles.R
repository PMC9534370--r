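# Independent brute-force oracles for the preprocessing predicates and the
# ANOVA-based ICC. Deliberately written as plain loops over the rule text,
# sharing no code with the package implementation.

# Evaluate the peak predicate at every window offset by direct computation,
# then apply the documented merge rule (chain clusters within the merge
# radius; keep the largest amplitude, earliest on ties).
oracle_detect_peaks <- function(signal, fs, s1_len = 100L, s2_len = 20L,
                                merge_window_s = 0.25) {
  n <- length(signal)
  raw <- integer(0)
  for (i in seq_len(n - s1_len + 1L)) {
    s1 <- signal[i:(i + s1_len - 1L)]
    m <- mean(s1)
    s2 <- s1[(s1_len - s2_len + 1L):s1_len]
    if (s2[1] < m && s2[s2_len] < m && max(s2) > m) {
      raw <- c(raw, i + (s1_len - s2_len) + which.max(s2) - 1L)
    }
  }
  raw <- sort(unique(raw))
  if (length(raw) <= 1L) return(raw)
  merged <- integer(0)
  cluster <- raw[1]
  for (j in 2:length(raw)) {
    if ((raw[j] - cluster[length(cluster)]) / fs > merge_window_s) {
      best <- cluster[signal[cluster] == max(signal[cluster])][1]
      merged <- c(merged, best)
      cluster <- raw[j]
    } else {
      cluster <- c(cluster, raw[j])
    }
  }
  best <- cluster[signal[cluster] == max(signal[cluster])][1]
  c(merged, best)
}

# Re-evaluate every 6-peak run from the rule text and return the stable
# sample mask.
oracle_stability_mask <- function(peaks, n, fs, run_len = 6L) {
  mask <- rep(FALSE, n)
  np <- length(peaks)
  if (np >= run_len) {
    for (j in 1:(np - run_len + 1L)) {
      run <- peaks[j:(j + run_len - 1L)]
      I <- diff(run) / fs
      i_ave <- sum(I) / length(I)
      d <- sqrt(sum((I - i_ave)^2) / length(I))
      ok <- (i_ave >= 0.6) && (i_ave <= 1.2) && (d < 0.2)
      if (ok) {
        for (iv in I) {
          if (iv < 0.9 * i_ave || iv > 1.1 * i_ave) ok <- FALSE
        }
      }
      if (ok) mask[run[1]:(run[run_len] - 1L)] <- TRUE
    }
  }
  mask
}

stability_df_to_mask <- function(segs, n) {
  mask <- rep(FALSE, n)
  for (i in which(segs$stable)) {
    if (segs$end[i] > segs$start[i]) {
      mask[segs$start[i]:(segs$end[i] - 1L)] <- TRUE
    }
  }
  mask
}

# ICC(3,1) through R's ANOVA machinery rather than explicit sums of squares.
oracle_icc31 <- function(pred, obs) {
  n <- length(obs)
  d <- data.frame(y = c(obs, pred),
                  target = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(c("obs", "pred"), each = n)))
  ms <- summary(stats::aov(y ~ target + rater, data = d))[[1]][["Mean Sq"]]
  ms_rows <- ms[1]
  ms_err <- ms[3]
  (ms_rows - ms_err) / (ms_rows + ms_err)
}

# A clean quasi-periodic pulse train for detector tests: sharp triangular
# beats on a flat baseline (shape unrelated to the generator's).
make_pulse_train <- function(n, fs, ibi_s, jitter_sd = 0, width_s = 0.2,
                             seed = 1) {
  set.seed(seed)
  x <- rep(0, n)
  apexes <- integer(0)
  t <- ibi_s
  while (TRUE) {
    t_next <- t + ibi_s + if (jitter_sd > 0) rnorm(1, 0, jitter_sd) else 0
    apex <- round(t * fs)
    if (apex > n - 1) break
    half <- max(2L, round(width_s * fs / 2))
    for (k in -half:half) {
      i <- apex + k
      if (i >= 1 && i <= n) x[i] <- max(x[i], 1 - abs(k) / half)
    }
    apexes <- c(apexes, apex)
    t <- t_next
  }
  list(signal = x, apexes = apexes)
}
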