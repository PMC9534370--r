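test_that("pulse generation is deterministic under seed and varies across seeds", {
  cfg <- pm_synth_config(duration_s = 30, seed = 3)
  a <- pm_generate_pulse_wave(5L, cfg, seed = 9)
  b <- pm_generate_pulse_wave(5L, cfg, seed = 9)
  c <- pm_generate_pulse_wave(5L, cfg, seed = 10)
  expect_identical(a$signal, b$signal)
  expect_identical(a$beats, b$beats)
  expect_false(identical(a$signal, c$signal))
})

test_that("noise-free beat train has exactly the configured interval", {
  cfg <- pm_synth_config(duration_s = 30, base_ibi_s = 0.8,
                         ibi_jitter_sd_s = 0, coupling = zero_coupling())
  w <- pm_generate_pulse_wave(7L, cfg, seed = 1)
  expect_true(all(w$beats$interval_s == 0.8))
})

test_that("rise fraction one half gives beats symmetric about the apex", {
  beats <- data.frame(onset_s = 0, interval_s = 1, rise_fraction = 0.5)
  fs <- 100
  sig <- painmeter:::pm_beats_to_signal(beats, fs, 101, amplitude = 1,
                                        baseline = 0, sharpness = 8)
  apex <- 51L  # t = 0.5 s
  for (k in 1:40) {
    expect_equal(sig[apex - k], sig[apex + k], tolerance = 1e-12)
  }
})

test_that("coupling monotonically shifts targeted quantities", {
  cfg <- pm_synth_config(duration_s = 60, ibi_jitter_sd_s = 0,
                         morph_noise_sd = 0, temp_noise_sd = 0,
                         temp_drift_amp = 0)
  ibis <- vapply(c(0L, 5L, 10L), function(p) {
    mean(pm_generate_pulse_wave(p, cfg, seed = 4)$beats$interval_s)
  }, numeric(1))
  expect_true(all(diff(ibis) < 0))  # negative ibi coupling: pain speeds pulse
  rfs <- vapply(c(0L, 5L, 10L), function(p) {
    mean(pm_generate_pulse_wave(p, cfg, seed = 4)$beats$rise_fraction)
  }, numeric(1))
  expect_true(all(diff(rfs) > 0))
})

test_that("artifact injection with an empty span list is the identity", {
  x <- sin(seq(0, 20, by = 0.01))
  spans <- data.frame(start = integer(0), end = integer(0))
  expect_identical(pm_inject_artifacts(x, spans, "noise_burst"), x)
})

test_that("dropout flattens the span and the detector finds no peaks there", {
  cfg <- pm_synth_config(duration_s = 60, seed = 2, morph_noise_sd = 0)
  w <- pm_generate_pulse_wave(5L, cfg, seed = 2)
  spans <- data.frame(start = 1001L, end = 2334L)  # a 20-second hole
  y <- pm_inject_artifacts(w$signal, spans, "dropout", fs = cfg$fs, seed = 3)
  expect_true(all(y[1001:2333] == y[1001]))
  expect_identical(y[-(1001:2333)], w$signal[-(1001:2333)])
  pk <- pm_detect_peaks(y, cfg$fs)
  expect_false(any(pk > 1100 & pk < 2233))
})

test_that("a noise-burst span is classified unstable downstream", {
  cfg <- pm_synth_config(duration_s = 120, seed = 6)
  w <- pm_generate_pulse_wave(4L, cfg, seed = 6)
  n <- length(w$signal)
  spans <- data.frame(start = 3001L, end = 3001L + round(20 * cfg$fs))
  y <- pm_inject_artifacts(w$signal, spans, "noise_burst", fs = cfg$fs,
                           seed = 8)
  segs <- pm_classify_stability(pm_detect_peaks(y, cfg$fs), n, cfg$fs)
  mask <- stability_df_to_mask(segs, n)
  inside <- mask[3001:(3000 + round(20 * cfg$fs))]
  expect_lt(mean(inside), 0.05)  # essentially the whole span unstable
})

test_that("overlapping artifact spans are merged with a warning", {
  x <- rnorm(1000)
  spans <- data.frame(start = c(100L, 150L), end = c(200L, 300L))
  expect_warning(pm_inject_artifacts(x, spans, "dropout"), "merged")
})

test_that("temperature coupling obeys the generative arithmetic", {
  cfg <- pm_synth_config(duration_s = 60, temp_noise_sd = 0,
                         temp_drift_amp = 0, morph_noise_sd = 0,
                         coupling = list(temp_forehead = -0.2))
  gen <- pm_generate_recording(pain = c(0L, 10L), cfg = cfg, seed = 5)
  tf <- gen$recording$temperature$forehead
  n <- length(tf)
  tt <- (seq_len(n) - 1) / cfg$fs  # latent pain switches at t = 30 s
  first <- mean(tf[tt < 30])
  second <- mean(tf[tt >= 30])
  expect_equal(first - second, 2.0, tolerance = 1e-9)
})

test_that("artifact-free recordings are almost entirely stable", {
  cfg <- pm_synth_config(duration_s = 120, artifact_fraction = 0, seed = 11)
  gen <- pm_generate_recording(pain = c(5L, 5L), cfg = cfg, seed = 11)
  prep <- pm_preprocess_recording(gen$recording, sensors = "temple")
  st <- prep$segments$temple
  frac <- sum((st$end - st$start)[st$stable]) / pm_n_samples(gen$recording)
  expect_gte(frac, 0.95)
})

test_that("cohort generation writes the right counts, reproducibly", {
  cfg <- pm_synth_config(n_subjects = 3, recordings_per_subject = 4,
                         duration_s = 15, seed = 21)
  d <- withr::local_tempdir()
  out <- pm_generate_cohort(cfg, out_dir = d)
  expect_identical(nrow(out$manifest), 12L)
  expect_identical(anyDuplicated(out$manifest$recording_id), 0L)
  expect_true(all(file.exists(out$manifest$path)))
  m <- pm_read_manifest(file.path(d, "manifest.tsv"))
  expect_identical(nrow(m), 12L)

  in1 <- pm_generate_cohort(cfg)
  in2 <- pm_generate_cohort(cfg)
  expect_identical(in1$manifest, in2$manifest)
  expect_identical(in1$recordings[[5]]$pulse, in2$recordings[[5]]$pulse)
  expect_identical(in1$truth, in2$truth)
})
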