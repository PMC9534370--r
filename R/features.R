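# Height-invariant pulse-width features and window temperature features.
#
# All pulse features depend only on peak/valley timing, never on amplitude,
# because how tightly the device is worn rescales the waveform. Window
# aggregation uses the population SD (divide by n), the convention fixed
# for the whole preprocessing/feature stage.

pm_pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-pulse width parameters
#'
#' For each complete pulse (start valley, peak, end valley): `L_R` is the
#' rising width (valley to peak), `L_F` the falling width (peak to valley),
#' both in seconds; `PPI_H` is the interval between consecutive high peaks
#' and `PPI_L` between consecutive low valleys, each defined between
#' adjacent pulses (so `k` pulses give `k - 1` PPI values). All outputs are
#' invariant to any positive affine rescaling of the signal amplitude.
#'
#' @param pulses data.frame from [pm_segment_pulses()].
#' @param fs sampling rate in Hz.
#' @return list with numeric vectors `lr`, `lf`, `ppi_h`, `ppi_l`.
#' @export
pm_compute_pulse_params <- function(pulses, fs) {
  k <- nrow(pulses)
  list(
    lr = (pulses$peak - pulses$start) / fs,
    lf = (pulses$end - pulses$peak) / fs,
    ppi_h = if (k >= 2) diff(pulses$peak) / fs else numeric(0),
    ppi_l = if (k >= 2) diff(pulses$start) / fs else numeric(0)
  )
}

#' Feature vector for one 10-second window
#'
#' Aggregates, per pulse sensor in the active combination, the mean and
#' (population) SD of each pulse parameter -- the SD of `PPI_H` is the
#' pulse-rate-variability feature -- plus the mean temperature at each of
#' the five sites and the four derived temperature features
#' `temple/finger`, `temple - finger`, `forehead/finger`,
#' `forehead - finger`. A window needs at least 2 complete pulses on every
#' requested sensor (otherwise the PPI features are undefined and the
#' window is dropped: the function returns `NULL`).
#'
#' @param rec a `pm_recording`.
#' @param window one-row window (list or data.frame row with `start`,
#'   `end`).
#' @param peaks named list of per-channel full-recording peak indices.
#' @param sensors active pulse-sensor combination.
#' @param temp_sd also include per-window temperature SDs (off by default;
#'   the feature list uses temperature means only).
#' @return named numeric vector of features, or `NULL` if the window lacks
#'   2 complete pulses on some sensor.
#' @export
pm_window_features <- function(rec, window, peaks, sensors = PM_PULSE_SENSORS,
                               temp_sd = FALSE) {
  idx <- window$start:(window$end - 1L)
  out <- numeric(0)
  for (s in sensors) {
    pk <- peaks[[s]]
    pk <- pk[pk >= window$start & pk < window$end]
    pulses <- pm_segment_pulses(rec$pulse[[s]], pk)
    if (nrow(pulses) < 2L) return(NULL)
    pp <- pm_compute_pulse_params(pulses, rec$fs)
    v <- c(mean(pp$lr), pm_pop_sd(pp$lr),
           mean(pp$lf), pm_pop_sd(pp$lf),
           mean(pp$ppi_h), pm_pop_sd(pp$ppi_h),
           mean(pp$ppi_l), pm_pop_sd(pp$ppi_l))
    names(v) <- paste0(s, "_", rep(c("LR", "LF", "PPIH", "PPIL"), each = 2),
                       "_", rep(c("mean", "sd"), 4))
    out <- c(out, v)
  }
  tmean <- vapply(PM_TEMP_SITES, function(s) mean(rec$temperature[[s]][idx]),
                  numeric(1))
  names(tmean) <- paste0("temp_", PM_TEMP_SITES, "_mean")
  out <- c(out, tmean)
  if (temp_sd) {
    tsd <- vapply(PM_TEMP_SITES, function(s) pm_pop_sd(rec$temperature[[s]][idx]),
                  numeric(1))
    names(tsd) <- paste0("temp_", PM_TEMP_SITES, "_sd")
    out <- c(out, tsd)
  }
  tf <- tmean[["temp_finger_mean"]]
  if (tf == 0) {
    warning("window has zero mean finger temperature; ratio features set NA")
    ratio_tf <- NA_real_
    ratio_ff <- NA_real_
  } else {
    ratio_tf <- tmean[["temp_temple_mean"]] / tf
    ratio_ff <- tmean[["temp_forehead_mean"]] / tf
  }
  out <- c(out,
           temp_ratio_temple_finger = ratio_tf,
           temp_diff_temple_finger = tmean[["temp_temple_mean"]] - tf,
           temp_ratio_forehead_finger = ratio_ff,
           temp_diff_forehead_finger = tmean[["temp_forehead_mean"]] - tf)
  out
}

#' Assign half-recording pain labels to windows
#'
#' Windows whose midpoint falls before the recording midpoint receive the
#' start score, the rest the end score (a midpoint exactly at half duration
#' counts as second half, the half-open convention).
#'
#' @param windows data.frame with `start`, `end` sample spans.
#' @param rec the recording the windows belong to.
#' @return `windows` with added `half` and `label` columns.
#' @export
pm_assign_pain_labels <- function(windows, rec) {
  if (!nrow(windows)) {
    windows$half <- character(0)
    windows$label <- integer(0)
    return(windows)
  }
  mid_t <- (windows$start - 1 + (windows$end - windows$start) / 2) / rec$fs
  windows$half <- ifelse(mid_t < rec$duration_s / 2, "first", "second")
  windows$label <- ifelse(windows$half == "first", rec$pain_start,
                          rec$pain_end)
  windows
}

#' Extract the labeled feature table for one recording
#'
#' Preprocesses the recording (unless a preprocessing result is supplied),
#' assigns half-recording pain labels, and computes the feature vector of
#' every usable window. Windows without 2 complete pulses on every active
#' sensor are dropped; the count of dropped windows is attached as the
#' `"n_dropped"` attribute.
#'
#' @param rec a `pm_recording`.
#' @param sensors active pulse-sensor combination.
#' @param prep optional result of [pm_preprocess_recording()] for these
#'   sensors.
#' @param temp_sd include temperature SD features.
#' @return data.frame: `recording_id`, `subject_id`, `half`, `label`, then
#'   one column per feature.
#' @export
pm_recording_features <- function(rec, sensors = PM_PULSE_SENSORS,
                                  prep = NULL, temp_sd = FALSE) {
  if (is.null(prep)) prep <- pm_preprocess_recording(rec, sensors)
  windows <- pm_assign_pain_labels(prep$windows, rec)
  rows <- vector("list", nrow(windows))
  kept <- logical(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    fv <- pm_window_features(rec, windows[i, ], prep$peaks, sensors, temp_sd)
    if (!is.null(fv)) {
      rows[[i]] <- fv
      kept[i] <- TRUE
    }
  }
  feat <- do.call(rbind, rows[kept])
  meta <- data.frame(
    recording_id = rep(rec$recording_id, sum(kept)),
    subject_id = rep(rec$subject_id, sum(kept)),
    half = windows$half[kept],
    label = windows$label[kept],
    stringsAsFactors = FALSE)
  out <- if (sum(kept)) cbind(meta, as.data.frame(feat)) else meta
  attr(out, "n_dropped") <- sum(!kept)
  out
}

#' Names of the feature columns in a feature table
#' @param features a feature table.
#' @return character vector of feature column names (everything except the
#'   provenance/label columns).
#' @export
pm_feature_cols <- function(features) {
  setdiff(names(features), c("recording_id", "subject_id", "half", "label"))
}

#' Fit a z-score normalization on training rows and apply it to both sets
#'
#' Centers and scales are estimated on the training set only (per CV fold,
#' so no test statistics leak into training); features with zero training
#' variance are dropped from both sets.
#'
#' @param train,test feature tables sharing the same feature columns;
#'   `test` may be `NULL`.
#' @param feature_cols which columns to normalize (default: all feature
#'   columns of `train`).
#' @return list with `train`, `test` (normalized), and `params`
#'   (data.frame of feature, center, scale for the retained features).
#' @export
pm_fit_apply_zscore <- function(train, test = NULL,
                                feature_cols = pm_feature_cols(train)) {
  if (!nrow(train)) stop("empty training set", call. = FALSE)
  center <- vapply(train[feature_cols], mean, numeric(1))
  scale_ <- vapply(train[feature_cols], stats::sd, numeric(1))
  keep <- is.finite(scale_) & scale_ > 0
  dropped <- feature_cols[!keep]
  feature_cols <- feature_cols[keep]
  center <- center[keep]
  scale_ <- scale_[keep]
  norm <- function(df) {
    df <- df[, setdiff(names(df), dropped), drop = FALSE]
    for (j in seq_along(feature_cols)) {
      df[[feature_cols[j]]] <- (df[[feature_cols[j]]] - center[j]) / scale_[j]
    }
    df
  }
  list(train = norm(train),
       test = if (!is.null(test)) norm(test) else NULL,
       params = data.frame(feature = feature_cols, center = unname(center),
                           scale = unname(scale_), stringsAsFactors = FALSE),
       dropped = dropped)
}
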