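# Pulse preprocessing: moving-average peak detection, 6-peak stability
# classification, unstable-segment removal, 10-second windowing, and
# per-pulse segmentation.
#
# Conventions fixed here and used throughout: sample indices are 1-based;
# spans are half-open [start, end); interval SDs are population SDs
# (divide by n); durations convert through fs.

#' Detect pulse peaks with the sliding moving-average rule
#'
#' A 100-sample window S1 (about 1.5 s at 66.67 Hz) slides one sample at a
#' time; `m` is the mean of S1 and S2 is the last 20 samples (about 0.3 s)
#' of S1. A peak is declared when the first and last values of S2 are below
#' `m` and the maximum of S2 exceeds `m`; the peak position is the index of
#' that maximum. Overlapping windows re-detect the same apex, so detections
#' whose positions lie within `merge_window_s` of each other are merged to
#' the one with the largest amplitude (ties to the earliest index);
#' 0.25 s is below half the minimum physiological inter-beat interval, so
#' distinct beats are never merged.
#'
#' @param signal numeric vector, at least `s1_len` samples.
#' @param fs sampling rate in Hz.
#' @param s1_len,s2_len moving-average and comparison window lengths in
#'   samples (defaults 100 and 20).
#' @param merge_window_s merge radius for duplicate detections, seconds.
#' @return sorted integer vector of peak sample indices (1-based).
#' @export
pm_detect_peaks <- function(signal, fs, s1_len = 100L, s2_len = 20L,
                            merge_window_s = 0.25) {
  n <- length(signal)
  if (n < s1_len) {
    stop("signal has ", n, " samples; peak detection needs at least ",
         s1_len, call. = FALSE)
  }
  starts <- seq_len(n - s1_len + 1L)
  cs <- c(0, cumsum(signal))
  m <- (cs[starts + s1_len] - cs[starts]) / s1_len
  first_i <- starts + (s1_len - s2_len)
  last_i <- starts + s1_len - 1L
  cand <- which(signal[first_i] < m & signal[last_i] < m)
  if (!length(cand)) return(integer(0))
  peak_idx <- integer(length(cand))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    a <- first_i[cand[j]]
    b <- last_i[cand[j]]
    w <- which.max(signal[a:b])
    if (signal[a + w - 1L] > m[cand[j]]) {
      keep[j] <- TRUE
      peak_idx[j] <- a + w - 1L
    }
  }
  pm_merge_peaks(sort(unique(peak_idx[keep])), signal, fs, merge_window_s)
}

# Chain-merge candidate peak indices: indices within merge_window_s seconds
# of their predecessor join its cluster; each cluster is represented by its
# largest-amplitude index (earliest on ties).
pm_merge_peaks <- function(idx, signal, fs, merge_window_s = 0.25) {
  if (length(idx) <= 1L) return(idx)
  gap <- diff(idx) / fs
  cluster <- cumsum(c(1L, as.integer(gap > merge_window_s)))
  out <- vapply(split(idx, cluster), function(ii) {
    ii[which.max(signal[ii])]
  }, integer(1))
  unname(out)
}

#' Classify the time axis into stable and unstable spans
#'
#' Every run of 6 consecutive detected peaks is tested: with the 5
#' inter-peak times `I` (seconds), their mean `I_ave` and population SD
#' `d`, the run is stable iff `0.6 <= I_ave <= 1.2`, `d < 0.2`, and every
#' `I` lies within `0.9 * I_ave` to `1.1 * I_ave`. Runs advance one peak at
#' a time (overlapping); a sample is stable iff it is covered by at least
#' one fully stable run, whose extent is `[first peak, last peak)`. The
#' tails before the first and after the last peak are unstable, as are
#' peak-free regions. With fewer than 6 peaks the whole recording is
#' unstable (with a warning).
#'
#' @param peaks sorted integer vector of peak indices from
#'   [pm_detect_peaks()].
#' @param n signal length in samples.
#' @param fs sampling rate in Hz.
#' @param iave_range allowed range of the mean inter-peak time (seconds).
#' @param d_max strict upper bound on the interval SD (seconds).
#' @param i_ratio allowed range of `I / I_ave`.
#' @param run_len number of peaks per run (default 6).
#' @return data.frame with columns `start`, `end` (half-open sample spans)
#'   and logical `stable`; the spans partition `[1, n + 1)` and adjacent
#'   spans never share a label.
#' @export
pm_classify_stability <- function(peaks, n, fs,
                                  iave_range = c(0.6, 1.2), d_max = 0.2,
                                  i_ratio = c(0.9, 1.1), run_len = 6L) {
  stable_mask <- logical(n)
  np <- length(peaks)
  if (np < run_len) {
    warning("fewer than ", run_len,
            " peaks detected; whole recording classified unstable")
  } else {
    intervals <- diff(peaks) / fs
    for (j in seq_len(np - run_len + 1L)) {
      I <- intervals[j:(j + run_len - 2L)]
      i_ave <- mean(I)
      d <- sqrt(mean((I - i_ave)^2))  # population SD
      ok <- i_ave >= iave_range[1] && i_ave <= iave_range[2] &&
        d < d_max &&
        all(I >= i_ratio[1] * i_ave) && all(I <= i_ratio[2] * i_ave)
      if (ok) {
        stable_mask[peaks[j]:(peaks[j + run_len - 1L] - 1L)] <- TRUE
      }
    }
  }
  r <- rle(stable_mask)
  end <- cumsum(r$lengths) + 1L
  start <- c(1L, end[-length(end)])
  data.frame(start = start, end = end, stable = r$values)
}

#' Intersect stable spans across a set of pulse channels
#'
#' A window is usable only if every sensor in the active combination is
#' stable over it, so the usable time axis is the intersection of the
#' channels' stable spans (sample counts can only shrink as sensors are
#' added).
#'
#' @param segs named list of stability data.frames from
#'   [pm_classify_stability()], one per channel.
#' @param channels channel names to intersect (non-empty subset of
#'   `names(segs)`).
#' @return data.frame with `start`, `end` columns: maximal half-open spans
#'   stable for every requested channel.
#' @export
pm_remove_unstable <- function(segs, channels) {
  if (!length(channels)) stop("empty channel set", call. = FALSE)
  missing <- setdiff(channels, names(segs))
  if (length(missing)) {
    stop("no stability segments for channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- max(segs[[channels[1]]]$end) - 1L
  mask <- rep(TRUE, n)
  for (ch in channels) {
    sg <- segs[[ch]]
    chmask <- logical(n)
    for (i in which(sg$stable)) {
      if (sg$end[i] > sg$start[i]) {
        chmask[sg$start[i]:(sg$end[i] - 1L)] <- TRUE
      }
    }
    mask <- mask & chmask
  }
  r <- rle(mask)
  end <- cumsum(r$lengths) + 1L
  start <- c(1L, end[-length(end)])
  data.frame(start = start, end = end)[r$values, , drop = FALSE]
}

#' Tile stable spans with contiguous 10-second windows
#'
#' Each span is tiled left to right with non-overlapping windows of
#' `round(window_s * fs)` samples; the remainder shorter than one window is
#' discarded, and windows never straddle a gap between spans.
#'
#' @param spans data.frame with `start`, `end` half-open sample spans.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 10).
#' @return data.frame with `start`, `end` columns, one row per window.
#' @export
pm_split_samples <- function(spans, fs, window_s = 10) {
  len <- as.integer(round(window_s * fs))
  out_start <- integer(0)
  for (i in seq_len(nrow(spans))) {
    k <- (spans$end[i] - spans$start[i]) %/% len
    if (k > 0) {
      out_start <- c(out_start, spans$start[i] + len * (seq_len(k) - 1L))
    }
  }
  data.frame(start = out_start, end = out_start + len)
}

#' Segment a window into individual pulses
#'
#' The valley between each adjacent peak pair is the minimum strictly
#' between them (earliest index on ties). A complete pulse is
#' (start valley, peak, end valley); the first and last partial pulses,
#' which lack a bounding valley, are dropped, so `n` peaks yield `n - 2`
#' pulses.
#'
#' @param signal the window's signal (full-recording coordinates are fine;
#'   indices in `peaks` must refer to `signal`).
#' @param peaks sorted integer peak indices inside the window.
#' @return data.frame with columns `start`, `peak`, `end` (sample indices);
#'   zero rows when fewer than 2 peaks are available.
#' @export
pm_segment_pulses <- function(signal, peaks) {
  peaks <- as.integer(peaks)
  np <- length(peaks)
  empty <- data.frame(start = integer(0), peak = integer(0), end = integer(0))
  if (np < 2L) return(empty)
  valleys <- integer(np - 1L)
  for (i in seq_len(np - 1L)) {
    a <- peaks[i] + 1L
    b <- peaks[i + 1L] - 1L
    if (b < a) return(empty)  # degenerate: adjacent peaks with no interior
    valleys[i] <- a + which.min(signal[a:b]) - 1L
  }
  if (np < 3L) return(empty)
  data.frame(start = valleys[-(np - 1L)],
             peak = peaks[2:(np - 1L)],
             end = valleys[-1L])
}

#' Full preprocessing of one recording
#'
#' Runs peak detection and stability classification on every requested
#' pulse channel, intersects the stable spans, and tiles them into
#' 10-second windows.
#'
#' @param rec a `pm_recording`.
#' @param sensors pulse sensors required to be jointly stable (default all
#'   three).
#' @param window_s window length in seconds.
#' @return list with `peaks` (named list of per-channel peak indices),
#'   `segments` (named list of stability data.frames), `stable_spans`
#'   (intersection), and `windows` (data.frame `start`, `end`, `half`;
#'   `half` is `"first"` when the window midpoint falls before the
#'   recording midpoint, else `"second"`).
#' @export
pm_preprocess_recording <- function(rec, sensors = PM_PULSE_SENSORS,
                                    window_s = 10) {
  n <- pm_n_samples(rec)
  peaks <- list()
  segments <- list()
  for (s in sensors) {
    pk <- pm_detect_peaks(rec$pulse[[s]], rec$fs)
    peaks[[s]] <- pk
    segments[[s]] <- suppressWarnings(
      pm_classify_stability(pk, n, rec$fs))
  }
  spans <- pm_remove_unstable(segments, sensors)
  windows <- pm_split_samples(spans, rec$fs, window_s)
  if (nrow(windows)) {
    mid_t <- (windows$start - 1 + (windows$end - windows$start) / 2) / rec$fs
    windows$half <- ifelse(mid_t < rec$duration_s / 2, "first", "second")
  } else {
    windows$half <- character(0)
  }
  list(peaks = peaks, segments = segments, stable_spans = spans,
       windows = windows)
}
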