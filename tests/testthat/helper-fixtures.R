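# Shared fixture builders (all generated in code at test time).

zero_coupling <- function() {
  list(rise_fraction = 0, ibi = 0, ibi_jitter_sd = 0,
       temp_forehead = 0, temp_temple = 0, temp_wrist_top = 0,
       temp_wrist_bottom = 0, temp_finger = 0)
}

# A small labeled feature table with a known linear label-feature link,
# built directly (no signal synthesis) for model/evaluation unit tests.
make_feature_table <- function(n_recordings = 5, windows_per_rec = 6,
                               n_features = 4, beta = NULL, noise_sd = 0,
                               n_subjects = 1, seed = 1) {
  set.seed(seed)
  if (is.null(beta)) beta <- c(2, -1, rep(0, n_features - 2))
  rows <- n_recordings * windows_per_rec
  x <- matrix(rnorm(rows * n_features), rows, n_features)
  colnames(x) <- paste0("f", seq_len(n_features))
  y <- drop(5 + x %*% beta) + rnorm(rows, 0, noise_sd)
  rec <- rep(sprintf("r%02d", seq_len(n_recordings)), each = windows_per_rec)
  subj <- rep(sprintf("s%02d", rep_len(seq_len(n_subjects), n_recordings)),
              each = windows_per_rec)
  cbind(
    data.frame(recording_id = rec, subject_id = subj,
               half = rep_len(c("first", "second"), rows), label = y,
               stringsAsFactors = FALSE),
    as.data.frame(x))
}

# A minimal valid recording with user-supplied channel builders.
make_recording <- function(duration_s = 30, fs = 10,
                           pulse_fun = function(n) rep(0.5, n),
                           temp_value = 33,
                           pain = c(3L, 5L), id = "recA", subject = "s01") {
  n <- round(fs * duration_s)
  sensors <- c("temple", "carotid", "finger")
  pulse <- setNames(lapply(sensors, function(s) pulse_fun(n)), sensors)
  temps <- c("forehead", "temple", "wrist_top", "wrist_bottom", "finger")
  temperature <- setNames(lapply(seq_along(temps), function(i) {
    rep(temp_value[min(i, length(temp_value))], n)
  }), temps)
  pm_recording(subject_id = subject, recording_id = id, fs = fs,
               pulse = pulse, temperature = temperature,
               pain_start = pain[1], pain_end = pain[2],
               duration_s = duration_s)
}
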