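# Synthetic Pain-Meter cohorts with known pain -> physiology coupling.
#
# The generator's job is timing fidelity, not optical realism: every
# downstream feature depends only on peak/valley timing and temperature
# levels, so beats are synthesized as asymmetric two-arc (rise/fall)
# raised-cosine pulses with a sharpness exponent, and temperatures as slow
# baselines plus a pain-coupled step at the recording midpoint.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 12 subjects, 15 ten-minute recordings each at 66.67 Hz, inter-beat
#' intervals around 0.85 s, and integer pain scores 0--10 drawn from a
#' per-subject truncated Gaussian (so extreme scores are rarer).
#'
#' @param n_subjects,recordings_per_subject cohort dimensions.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param base_ibi_s mean inter-beat interval at pain 0 (seconds).
#' @param ibi_jitter_sd_s SD of beat-to-beat interval noise at pain 0.
#' @param rise_fraction_base fraction of each beat spent rising (0--1).
#' @param sharpness exponent on the raised-cosine arcs; larger values give a
#'   narrower systolic peak. The peak's above-mean width must stay below the
#'   detector's 0.3-s comparison window for peaks to be detectable, which a
#'   plain half-cosine (sharpness 1) does not satisfy at physiological beat
#'   intervals.
#' @param pulse_baseline,pulse_amplitude baseline level and named per-channel
#'   amplitudes of the pulse waveform (arbitrary units; all extracted pulse
#'   features are height-invariant).
#' @param morph_noise_sd per-channel white morphology noise SD (same units
#'   as amplitude).
#' @param temp_baseline named per-site baseline skin temperatures (deg C).
#' @param temp_noise_sd,temp_drift_amp,temp_drift_period_s white-noise SD and
#'   slow sinusoidal drift amplitude/period of the temperature channels.
#' @param subject_ibi_sd,subject_temp_sd SDs of the per-subject random
#'   effects on baseline inter-beat interval and temperatures.
#' @param coupling named list of slopes per unit pain: `rise_fraction`
#'   (fraction/point), `ibi` (s/point; negative = pain raises heart rate),
#'   `ibi_jitter_sd` (s/point), and `temp_<site>` (deg C/point).
#' @param artifact_fraction fraction of each recording corrupted by
#'   motion-artifact epochs, per pulse channel independently, in `[0, 1)`.
#' @param artifact_mode one of `"noise_burst"`, `"dropout"`,
#'   `"irregular_beats"`.
#' @param pain_score_process `"subject_gaussian"` (default; per-subject mean
#'   drawn uniformly in 2--8, scores discretized/truncated), `"iid"`
#'   (uniform integers 0--10, independent across recordings; the
#'   recording-exchangeable process assumed by the permutation null), or
#'   `"fixed"` (all scores equal `pain_fixed`).
#' @param pain_fixed score used when `pain_score_process = "fixed"`.
#' @param seed master integer seed.
#' @return a validated `pm_synth_config` list.
#' @export
pm_synth_config <- function(n_subjects = 12,
                            recordings_per_subject = 15,
                            duration_s = 600,
                            fs = PM_FS_DEFAULT,
                            base_ibi_s = 0.85,
                            ibi_jitter_sd_s = 0.012,
                            rise_fraction_base = 0.30,
                            sharpness = 8,
                            pulse_baseline = 0.2,
                            pulse_amplitude = c(temple = 1.0, carotid = 1.3,
                                                finger = 0.8),
                            morph_noise_sd = 0.01,
                            temp_baseline = c(forehead = 33.0, temple = 32.5,
                                              wrist_top = 31.5,
                                              wrist_bottom = 31.2,
                                              finger = 30.0),
                            temp_noise_sd = 0.05,
                            temp_drift_amp = 0.05,
                            temp_drift_period_s = 300,
                            subject_ibi_sd = 0.04,
                            subject_temp_sd = 0.3,
                            coupling = list(),
                            artifact_fraction = 0,
                            artifact_mode = c("noise_burst", "dropout",
                                              "irregular_beats"),
                            pain_score_process = c("subject_gaussian", "iid",
                                                   "fixed"),
                            pain_fixed = 5,
                            seed = 1L) {
  default_coupling <- list(
    rise_fraction = 0.008,
    ibi = -0.012,
    ibi_jitter_sd = 0.0015,
    temp_forehead = -0.03,
    temp_temple = -0.02,
    temp_wrist_top = -0.02,
    temp_wrist_bottom = -0.02,
    temp_finger = -0.12
  )
  cpl <- utils::modifyList(default_coupling, as.list(coupling))
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    recordings_per_subject = as.integer(recordings_per_subject),
    duration_s = duration_s,
    fs = fs,
    base_ibi_s = base_ibi_s,
    ibi_jitter_sd_s = ibi_jitter_sd_s,
    rise_fraction_base = rise_fraction_base,
    sharpness = sharpness,
    pulse_baseline = pulse_baseline,
    pulse_amplitude = pulse_amplitude,
    morph_noise_sd = morph_noise_sd,
    temp_baseline = temp_baseline,
    temp_noise_sd = temp_noise_sd,
    temp_drift_amp = temp_drift_amp,
    temp_drift_period_s = temp_drift_period_s,
    subject_ibi_sd = subject_ibi_sd,
    subject_temp_sd = subject_temp_sd,
    coupling = cpl,
    artifact_fraction = artifact_fraction,
    artifact_mode = match.arg(artifact_mode),
    pain_score_process = match.arg(pain_score_process),
    pain_fixed = as.integer(pain_fixed),
    seed = as.integer(seed)
  )
  if (cfg$rise_fraction_base <= 0 || cfg$rise_fraction_base >= 1) {
    stop("rise_fraction_base must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cfg$artifact_fraction < 0 || cfg$artifact_fraction >= 1) {
    stop("artifact_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$duration_s * cfg$fs < round(10 * cfg$fs)) {
    stop("duration_s too short to hold one 10-second window", call. = FALSE)
  }
  for (p in 0:10) {
    ibi <- cfg$base_ibi_s + cfg$coupling$ibi * p
    if (ibi <= 0 || ibi >= cfg$duration_s) {
      stop("coupling drives the inter-beat interval outside (0, duration_s) ",
           "at pain ", p, call. = FALSE)
    }
  }
  class(cfg) <- "pm_synth_config"
  cfg
}

# Latent pain at time t: first-half score before the midpoint, second-half
# score from the midpoint on (half-open convention shared with labeling).
pm_latent_pain <- function(t, duration_s, pain_start, pain_end) {
  ifelse(t < duration_s / 2, pain_start, pain_end)
}

# Draw the beat train for one recording. Pain switches at the midpoint.
# Returns data.frame(onset_s, interval_s, rise_fraction, pain).
pm_generate_beats <- function(pain_start, pain_end, cfg, duration_s,
                              ibi_offset = 0) {
  onsets <- numeric(0)
  intervals <- numeric(0)
  rfs <- numeric(0)
  pains <- integer(0)
  t <- 0
  n_guess <- ceiling(duration_s / max(0.3, cfg$base_ibi_s - 0.2)) + 8L
  draws <- rnorm(n_guess)
  i <- 0L
  while (t < duration_s) {
    i <- i + 1L
    if (i > length(draws)) draws <- c(draws, rnorm(n_guess))
    p <- pm_latent_pain(t, duration_s, pain_start, pain_end)
    mu <- cfg$base_ibi_s + cfg$coupling$ibi * p + ibi_offset
    sdv <- max(0, cfg$ibi_jitter_sd_s + cfg$coupling$ibi_jitter_sd * p)
    intv <- mu + sdv * draws[i]
    intv <- min(max(intv, 0.25), 2.5)  # physiological guard rails
    rf <- cfg$rise_fraction_base + cfg$coupling$rise_fraction * p
    rf <- min(max(rf, 0.05), 0.95)
    onsets <- c(onsets, t)
    intervals <- c(intervals, intv)
    rfs <- c(rfs, rf)
    pains <- c(pains, p)
    t <- t + intv
  }
  data.frame(onset_s = onsets, interval_s = intervals, rise_fraction = rfs,
             pain = pains)
}

# Render a beat train into a sampled waveform. Each beat rises over
# rise_fraction of its interval and falls over the remainder; both arcs are
# raised cosines to the sharpness power, so the unique per-beat minimum sits
# at the beat onset and the apex at onset + rise_fraction * interval. A
# small (2%) plain half-cosine component is mixed in so the waveform
# decreases strictly toward the onset at sample resolution: the pure
# sharpened arc underflows to the baseline near the valley, which would
# leave a flat tie region and shift the detected valley off the onset.
pm_beats_to_signal <- function(beats, fs, n, amplitude = 1,
                               baseline = 0.2, sharpness = 8,
                               smooth_mix = 0.02) {
  t <- (seq_len(n) - 1) / fs
  k <- findInterval(t, beats$onset_s)
  k[k < 1L] <- 1L
  phase <- (t - beats$onset_s[k]) / beats$interval_s[k]
  phase <- pmin(pmax(phase, 0), 1)
  rf <- beats$rise_fraction[k]
  u <- ifelse(phase <= rf, phase / rf, (phase - rf) / (1 - rf))
  arc <- ifelse(phase <= rf, (1 - cos(pi * u)) / 2, (1 + cos(pi * u)) / 2)
  g <- (1 - smooth_mix) * arc^sharpness + smooth_mix * arc
  baseline + amplitude * g
}

#' Generate one synthetic pulse waveform with per-beat ground truth
#'
#' @param pain integer pain score 0--10 held constant over the waveform.
#' @param cfg a [pm_synth_config()].
#' @param duration_s length in seconds (defaults to `cfg$duration_s`).
#' @param seed integer seed; the same seed reproduces the same waveform.
#' @return list with `signal` (numeric vector of `round(fs * duration_s)`
#'   samples) and `beats` (data.frame of per-beat onset, interval, rise
#'   fraction, and apex time `apex_s`).
#' @export
pm_generate_pulse_wave <- function(pain, cfg, duration_s = cfg$duration_s,
                                   seed = cfg$seed) {
  stopifnot(inherits(cfg, "pm_synth_config"))
  set.seed(seed)
  beats <- pm_generate_beats(pain, pain, cfg, duration_s)
  n <- as.integer(round(cfg$fs * duration_s))
  sig <- pm_beats_to_signal(beats, cfg$fs, n, amplitude = 1,
                            baseline = cfg$pulse_baseline,
                            sharpness = cfg$sharpness)
  if (cfg$morph_noise_sd > 0) sig <- sig + rnorm(n, sd = cfg$morph_noise_sd)
  beats$apex_s <- beats$onset_s + beats$rise_fraction * beats$interval_s
  list(signal = sig, beats = beats)
}

# Merge overlapping [start, end) spans (rows of a data.frame, sample indices).
pm_merge_spans <- function(spans, warn = TRUE) {
  if (!nrow(spans)) return(spans)
  spans <- spans[order(spans$start), , drop = FALSE]
  out <- spans[1, , drop = FALSE]
  overlapped <- FALSE
  for (i in seq_len(nrow(spans))[-1]) {
    last <- nrow(out)
    if (spans$start[i] <= out$end[last]) {
      if (spans$start[i] < out$end[last]) overlapped <- TRUE
      out$end[last] <- max(out$end[last], spans$end[i])
    } else {
      out <- rbind(out, spans[i, , drop = FALSE])
    }
  }
  if (overlapped && warn) warning("overlapping artifact spans were merged")
  out
}

#' Corrupt a signal inside given spans
#'
#' Alters the signal only inside the spans, in a way designed to violate the
#' stability rules: `"noise_burst"` replaces the span with white noise (no
#' quasi-periodic peaks), `"dropout"` flattens it, `"irregular_beats"`
#' substitutes a pulse train whose intervals fall far outside 0.9--1.1 times
#' any local mean.
#'
#' @param signal numeric vector.
#' @param spans data.frame with integer columns `start`, `end` (1-based,
#'   half-open `[start, end)` sample spans). Overlapping spans are merged
#'   with a warning.
#' @param mode artifact mode (see above).
#' @param fs sampling rate (needed for `"irregular_beats"`).
#' @param seed integer seed.
#' @return the corrupted signal.
#' @export
pm_inject_artifacts <- function(signal, spans,
                                mode = c("noise_burst", "dropout",
                                         "irregular_beats"),
                                fs = PM_FS_DEFAULT, seed = 1L) {
  mode <- match.arg(mode)
  if (!nrow(spans)) return(signal)
  if (any(spans$start < 1) || any(spans$end > length(signal) + 1)) {
    stop("artifact spans fall outside the signal extent", call. = FALSE)
  }
  spans <- pm_merge_spans(spans)
  set.seed(seed)
  amp <- stats::sd(signal)
  for (i in seq_len(nrow(spans))) {
    idx <- spans$start[i]:(spans$end[i] - 1L)
    if (mode == "noise_burst") {
      signal[idx] <- mean(signal[idx]) + rnorm(length(idx), sd = 1.5 * amp)
    } else if (mode == "dropout") {
      signal[idx] <- signal[spans$start[i]]
    } else {
      k <- ceiling(length(idx) / fs / 0.3) + 2L
      intv <- runif(k, 0.25, 0.45) * sample(c(1, 4), k, replace = TRUE)
      beats <- data.frame(onset_s = cumsum(c(0, intv[-k])), interval_s = intv,
                          rise_fraction = 0.3)
      signal[idx] <- pm_beats_to_signal(beats, fs, length(idx),
                                        amplitude = 2 * amp, baseline = 0,
                                        sharpness = 8) + mean(signal[idx])
    }
  }
  signal
}

# Draw random artifact spans totalling `fraction` of an n-sample signal,
# split over a few epochs.
pm_draw_artifact_spans <- function(n, fraction, fs) {
  if (fraction <= 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  total <- round(fraction * n)
  if (total < 1) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  k <- max(1L, min(3L, floor(total / round(5 * fs))))
  len <- diff(round(seq(0, total, length.out = k + 1)))
  len <- len[len > 0]
  starts <- sort(sample.int(n - max(len), length(len)))
  spans <- data.frame(start = starts, end = pmin(starts + len, n + 1L))
  pm_merge_spans(spans, warn = FALSE)
}

#' Generate one synthetic recording with full ground truth
#'
#' The three pulse channels share one beat train (channel-specific amplitude
#' and morphology noise); the five temperature channels are slow baselines
#' plus `coupling * pain` plus noise. The latent pain score switches from
#' `pain_start` to `pain_end` exactly at the midpoint, so the half-recording
#' label assignment used downstream is exactly correct in synthesis.
#'
#' @param subject list of subject-level effects: `subject_id`, `ibi_offset`
#'   (s), `temp_offset` (named per-site, deg C). Defaults to zero effects.
#' @param pain c(pain_start, pain_end) integer scores.
#' @param cfg a [pm_synth_config()].
#' @param seed integer seed.
#' @param recording_id identifier for the new recording.
#' @return list with `recording` (a `pm_recording`) and `truth` (beats,
#'   per-channel artifact spans, coupling, latent pain per half).
#' @export
pm_generate_recording <- function(subject = NULL, pain = c(5L, 5L), cfg,
                                  seed = cfg$seed, recording_id = "rec01") {
  stopifnot(inherits(cfg, "pm_synth_config"))
  if (is.null(subject)) {
    subject <- list(subject_id = "s01", ibi_offset = 0,
                    temp_offset = stats::setNames(rep(0, length(PM_TEMP_SITES)),
                                                  PM_TEMP_SITES))
  }
  set.seed(seed)
  n <- as.integer(round(cfg$fs * cfg$duration_s))
  tt <- (seq_len(n) - 1) / cfg$fs
  beats <- pm_generate_beats(pain[1], pain[2], cfg, cfg$duration_s,
                             ibi_offset = subject$ibi_offset)
  beats$apex_s <- beats$onset_s + beats$rise_fraction * beats$interval_s
  pain_t <- pm_latent_pain(tt, cfg$duration_s, pain[1], pain[2])

  pulse <- list()
  artifact_spans <- list()
  for (s in PM_PULSE_SENSORS) {
    sig <- pm_beats_to_signal(beats, cfg$fs, n,
                              amplitude = cfg$pulse_amplitude[[s]],
                              baseline = cfg$pulse_baseline,
                              sharpness = cfg$sharpness)
    if (cfg$morph_noise_sd > 0) sig <- sig + rnorm(n, sd = cfg$morph_noise_sd)
    spans <- pm_draw_artifact_spans(n, cfg$artifact_fraction, cfg$fs)
    if (nrow(spans)) {
      sig <- pm_inject_artifacts(sig, spans, mode = cfg$artifact_mode,
                                 fs = cfg$fs,
                                 seed = sample.int(2^30, 1))
    }
    pulse[[s]] <- sig
    artifact_spans[[s]] <- spans
  }

  temperature <- list()
  for (s in PM_TEMP_SITES) {
    base <- cfg$temp_baseline[[s]] + subject$temp_offset[[s]]
    drift <- cfg$temp_drift_amp *
      sin(2 * pi * tt / cfg$temp_drift_period_s + runif(1, 0, 2 * pi))
    cpl <- cfg$coupling[[paste0("temp_", s)]]
    temperature[[s]] <- base + drift + cpl * pain_t +
      rnorm(n, sd = cfg$temp_noise_sd)
  }

  rec <- pm_recording(
    subject_id = subject$subject_id, recording_id = recording_id,
    fs = cfg$fs, pulse = pulse, temperature = temperature,
    pain_start = as.integer(pain[1]), pain_end = as.integer(pain[2]),
    duration_s = cfg$duration_s)
  truth <- list(beats = beats, artifact_spans = artifact_spans,
                coupling = cfg$coupling,
                pain_start = as.integer(pain[1]), pain_end = as.integer(pain[2]))
  list(recording = rec, truth = truth)
}

# Draw per-subject random effects and the per-recording pain-score pairs for
# a whole cohort, deterministically from cfg$seed.
pm_cohort_plan <- function(cfg) {
  set.seed(cfg$seed)
  subjects <- lapply(seq_len(cfg$n_subjects), function(j) {
    list(
      subject_id = sprintf("s%02d", j),
      ibi_offset = min(max(rnorm(1, sd = cfg$subject_ibi_sd), -0.08), 0.08),
      temp_offset = stats::setNames(
        rnorm(length(PM_TEMP_SITES), sd = cfg$subject_temp_sd), PM_TEMP_SITES),
      pain_mu = runif(1, 2, 8)
    )
  })
  plan <- do.call(rbind, lapply(seq_len(cfg$n_subjects), function(j) {
    subj <- subjects[[j]]
    do.call(rbind, lapply(seq_len(cfg$recordings_per_subject), function(r) {
      pain <- switch(cfg$pain_score_process,
        subject_gaussian = {
          p1 <- min(max(round(rnorm(1, subj$pain_mu, 2)), 0), 10)
          p2 <- min(max(p1 + round(rnorm(1, 0, 1)), 0), 10)
          c(p1, p2)
        },
        iid = sample(0:10, 2, replace = TRUE),
        fixed = c(cfg$pain_fixed, cfg$pain_fixed))
      data.frame(
        subject_idx = j,
        subject_id = subj$subject_id,
        recording_id = sprintf("%s_r%02d", subj$subject_id, r),
        pain_start = pain[1], pain_end = pain[2],
        rec_seed = (cfg$seed + 7919L * (j * 1000L + r)) %% 2147483647L)
    }))
  }))
  list(subjects = subjects, plan = plan)
}

#' Generate a full synthetic cohort
#'
#' Draws subject-level random effects and pain-score pairs once, then
#' generates `n_subjects * recordings_per_subject` recordings. With
#' `out_dir` set, recordings are written in the on-disk format together with
#' a cohort manifest and per-recording ground-truth sidecars (beat times,
#' intervals, rise fractions, artifact spans); otherwise recordings are
#' returned in memory.
#'
#' @param cfg a [pm_synth_config()].
#' @param out_dir optional output directory.
#' @return list with `manifest` (data.frame), `recordings` (list of
#'   `pm_recording`, `NULL` when written to disk), and `truth` (list per
#'   recording).
#' @export
pm_generate_cohort <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pm_synth_config"))
  cp <- pm_cohort_plan(cfg)
  plan <- cp$plan
  keep <- is.null(out_dir)
  if (!keep) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  recordings <- if (keep) vector("list", nrow(plan)) else NULL
  truth <- vector("list", nrow(plan))
  paths <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    gen <- pm_generate_recording(
      subject = cp$subjects[[row$subject_idx]],
      pain = c(row$pain_start, row$pain_end),
      cfg = cfg, seed = row$rec_seed, recording_id = row$recording_id)
    truth[[i]] <- gen$truth
    if (keep) {
      recordings[[i]] <- gen$recording
    } else {
      paths[i] <- file.path(out_dir, paste0(row$recording_id, ".tsv"))
      pm_write_recording(gen$recording, paths[i])
      tr <- gen$truth$beats
      data.table::fwrite(tr, file.path(out_dir,
                                       paste0(row$recording_id, ".truth.tsv")),
                         sep = "\t", eol = "\n")
    }
  }
  names(truth) <- plan$recording_id
  if (keep) names(recordings) <- plan$recording_id
  manifest <- data.frame(subject_id = plan$subject_id,
                         recording_id = plan$recording_id,
                         path = if (keep) NA_character_ else paths,
                         pain_start = plan$pain_start,
                         pain_end = plan$pain_end,
                         stringsAsFactors = FALSE)
  if (!keep) {
    pm_write_manifest(manifest[, c("subject_id", "recording_id", "path")],
                      file.path(out_dir, "manifest.tsv"))
    data.table::fwrite(manifest, file.path(out_dir, "cohort_truth.tsv"),
                       sep = "\t", eol = "\n")
  }
  list(manifest = manifest, recordings = recordings, truth = truth)
}
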