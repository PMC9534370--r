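test_that("a constant signal yields no peaks and a too-short signal errors", {
  expect_identical(pm_detect_peaks(rep(1, 500), fs = 50), integer(0))
  expect_error(pm_detect_peaks(rnorm(99), fs = 50), "99")
})

test_that("a single isolated bump is detected exactly once, at its apex", {
  x <- rep(0, 600)
  apex <- 300L
  half <- 8L
  x[(apex - half):(apex + half)] <- 1 - abs(-half:half) / half
  got <- pm_detect_peaks(x, fs = 50)
  expect_identical(got, apex)
  expect_identical(got, oracle_detect_peaks(x, fs = 50))
})

test_that("detector matches the brute-force oracle on assorted signals", {
  set.seed(99)
  fs <- 66.67
  for (k in 1:6) {
    sig <- switch(1 + (k %% 3),
      rnorm(1500),
      make_pulse_train(1500, fs, ibi_s = 0.8, jitter_sd = 0.02,
                       seed = k)$signal + rnorm(1500, 0, 0.02),
      make_pulse_train(1500, fs, ibi_s = runif(1, 0.5, 1.3),
                       jitter_sd = 0.05, seed = k)$signal)
    expect_identical(pm_detect_peaks(sig, fs), oracle_detect_peaks(sig, fs))
  }
})

test_that("clean pulse trains are found beat for beat", {
  fs <- 66.67
  tr <- make_pulse_train(round(60 * fs), fs, ibi_s = 0.8, seed = 5)
  pk <- pm_detect_peaks(tr$signal, fs)
  expect_lte(abs(length(pk) - length(tr$apexes)), 1L)
  matched <- vapply(pk, function(p) min(abs(tr$apexes - p)), numeric(1))
  expect_true(all(matched <= 2))
})

test_that("stability thresholds behave as specified on exact interval trains", {
  fs <- 50
  mk <- function(intervals_s) cumsum(c(100L, round(intervals_s * fs)))
  n <- 5000L

  segs <- pm_classify_stability(mk(rep(0.8, 5)), n, fs)
  mask <- stability_df_to_mask(segs, n)
  pk <- mk(rep(0.8, 5))
  expect_true(all(mask[pk[1]:(pk[6] - 1L)]))
  expect_false(any(mask[1:(pk[1] - 1L)]))
  expect_false(any(mask[pk[6]:n]))

  segs <- pm_classify_stability(mk(rep(0.5, 5)), n, fs)
  expect_false(any(stability_df_to_mask(segs, n)))  # I_ave below 0.6 s

  # four 0.8-s intervals and one 0.96-s: 0.96 / I_ave = 1.154 > 1.1
  segs <- pm_classify_stability(mk(c(rep(0.8, 4), 0.96)), n, fs)
  expect_false(any(stability_df_to_mask(segs, n)))
})

test_that("fewer than six peaks classifies everything unstable with warning", {
  expect_warning(segs <- pm_classify_stability(c(10L, 50L), 200L, 50),
                 "unstable")
  expect_identical(segs$stable, FALSE)
  expect_identical(segs$start, 1L)
  expect_identical(segs$end, 201L)
})

test_that("stability classifier matches the brute-force oracle", {
  set.seed(7)
  fs <- 66.67
  for (k in 1:5) {
    sig <- make_pulse_train(2000, fs, ibi_s = runif(1, 0.55, 1.25),
                            jitter_sd = runif(1, 0, 0.12), seed = 10 + k)
    pk <- pm_detect_peaks(sig$signal, fs)
    segs <- suppressWarnings(pm_classify_stability(pk, 2000L, fs))
    expect_identical(stability_df_to_mask(segs, 2000L),
                     oracle_stability_mask(pk, 2000L, fs))
    # soundness: every reported stable sample is covered by a stable run
    expect_true(all(!stability_df_to_mask(segs, 2000L) |
                      oracle_stability_mask(pk, 2000L, fs)))
  }
})

test_that("stable-span intersection follows interval arithmetic", {
  seg_of <- function(stable_spans, n) {
    # build an alternating segments frame from stable [start,end) spans
    mask <- rep(FALSE, n)
    for (i in seq_len(nrow(stable_spans))) {
      mask[stable_spans$start[i]:(stable_spans$end[i] - 1L)] <- TRUE
    }
    r <- rle(mask)
    end <- cumsum(r$lengths) + 1L
    data.frame(start = c(1L, end[-length(end)]), end = end,
               stable = r$values)
  }
  n <- 500L
  a <- seg_of(data.frame(start = 1L, end = 301L), n)
  b <- seg_of(data.frame(start = 201L, end = 501L), n)
  both <- pm_remove_unstable(list(A = a, B = b), c("A", "B"))
  expect_identical(both$start, 201L)
  expect_identical(both$end, 301L)

  only_a <- pm_remove_unstable(list(A = a), "A")
  expect_identical(only_a$start, 1L)
  expect_identical(only_a$end, 301L)

  c_ <- seg_of(data.frame(start = 401L, end = 451L), n)
  none <- pm_remove_unstable(list(A = seg_of(data.frame(start = 1L, end = 101L), n),
                                  B = seg_of(data.frame(start = 201L, end = 301L), n),
                                  C = c_), c("A", "B", "C"))
  expect_identical(nrow(none), 0L)
  expect_identical(nrow(pm_split_samples(none, 50)), 0L)

  expect_error(pm_remove_unstable(list(A = a), character(0)), "empty")
})

test_that("window tiling floors span lengths and discards remainders", {
  fs <- 10
  spans <- function(lens_s) {
    start <- cumsum(c(1, head(round(lens_s * fs), -1) + 50L))
    data.frame(start = as.integer(start),
               end = as.integer(start + round(lens_s * fs)))
  }
  expect_identical(nrow(pm_split_samples(spans(35), fs)), 3L)
  expect_identical(nrow(pm_split_samples(spans(9.9), fs)), 0L)
  expect_identical(nrow(pm_split_samples(spans(c(12, 21)), fs)), 3L)
  w <- pm_split_samples(spans(c(12, 21)), fs)
  expect_true(all(w$end - w$start == 100L))
})

test_that("windowing conserves duration within one window per span", {
  set.seed(3)
  fs <- 66.67
  len <- round(10 * fs)
  for (k in 1:10) {
    lens <- sample(50:1500, sample(1:4, 1))
    start <- cumsum(c(1L, head(lens, -1) + sample(5:50, length(lens) - 1,
                                                  replace = TRUE)))
    spans <- data.frame(start = as.integer(start),
                        end = as.integer(start + lens))
    w <- pm_split_samples(spans, fs)
    expect_lte(sum(w$end - w$start), sum(lens))
    expect_lt(sum(lens) - sum(w$end - w$start), length(lens) * len)
    # windows never straddle a gap
    if (nrow(w)) {
      inside <- vapply(seq_len(nrow(w)), function(i) {
        any(w$start[i] >= spans$start & w$end[i] <= spans$end)
      }, logical(1))
      expect_true(all(inside))
    }
  }
})

test_that("pulse segmentation finds valleys and drops partial pulses", {
  fs <- 50
  tr <- make_pulse_train(1000, fs, ibi_s = 0.8, width_s = 0.3, seed = 2)
  pk <- tr$apexes
  pulses <- pm_segment_pulses(tr$signal, pk)
  expect_identical(nrow(pulses), length(pk) - 2L)
  expect_true(all(pulses$start < pulses$peak & pulses$peak < pulses$end))
  # symmetric triangular beats on a flat baseline: the flat stretch between
  # beats ties at zero, so the earliest interior minimum is taken
  first_valley <- pulses$start[1]
  between <- (pk[1] + 1):(pk[2] - 1)
  expect_identical(first_valley,
                   between[which.min(tr$signal[between])])
  expect_identical(nrow(pm_segment_pulses(tr$signal, pk[1])), 0L)
  expect_identical(nrow(pm_segment_pulses(tr$signal, pk[1:2])), 0L)
})

test_that("valley ties break to the earliest index", {
  x <- rep(1, 200)
  x[c(50, 100, 150)] <- 5
  x[70] <- 0
  x[90] <- 0   # two equal minima between the first peak pair
  x[120] <- 0
  pulses <- pm_segment_pulses(x, c(50L, 100L, 150L))
  expect_identical(pulses$start[1], 70L)
})
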