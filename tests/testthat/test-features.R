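test_that("pulse width parameters follow timing arithmetic", {
  fs <- 50
  pulses <- data.frame(start = c(100L, 140L, 180L),
                       peak = c(112L, 152L, 192L),
                       end = c(140L, 180L, 220L))
  pp <- pm_compute_pulse_params(pulses, fs)
  expect_equal(pp$lr, rep(12 / fs, 3))
  expect_equal(pp$lf, rep(28 / fs, 3))
  expect_equal(pp$ppi_h, rep(40 / fs, 2))
  expect_equal(pp$ppi_l, rep(40 / fs, 2))
  expect_true(all(c(pp$lr, pp$lf, pp$ppi_h, pp$ppi_l) > 0))
  expect_equal(pp$lr + pp$lf, (pulses$end - pulses$start) / fs)
})

test_that("noise-free constant-interval beats give zero PPI variability", {
  cfg <- pm_synth_config(duration_s = 40, base_ibi_s = 0.8,
                         ibi_jitter_sd_s = 0, morph_noise_sd = 0,
                         coupling = zero_coupling(), temp_noise_sd = 0,
                         temp_drift_amp = 0)
  gen <- pm_generate_recording(pain = c(5L, 5L), cfg = cfg, seed = 2)
  ft <- pm_recording_features(gen$recording, sensors = "temple")
  expect_gt(nrow(ft), 0)
  expect_true(all(abs(ft$temple_PPIH_mean - 0.8) <= 2 / cfg$fs))
  expect_true(all(ft$temple_PPIH_sd <= 1 / cfg$fs))
  expect_true(all(abs(ft$temple_PPIL_mean - 0.8) <= 2 / cfg$fs))
})

test_that("pulse features are invariant to positive affine amplitude changes", {
  cfg <- pm_synth_config(duration_s = 60, seed = 13)
  gen <- pm_generate_recording(pain = c(2L, 8L), cfg = cfg, seed = 13)
  rec <- gen$recording
  rec2 <- rec
  rec2$pulse$temple <- rec$pulse$temple * 3.7 + 10
  ft1 <- pm_recording_features(rec, sensors = "temple")
  ft2 <- pm_recording_features(rec2, sensors = "temple")
  pulse_cols <- grep("^temple_", names(ft1), value = TRUE)
  expect_identical(ft1[pulse_cols], ft2[pulse_cols])
})

test_that("derived temperature features follow their formulas", {
  rec <- make_recording(duration_s = 30, fs = 10,
                        pulse_fun = function(n) rep(0.5, n),
                        temp_value = c(33, 33, 31, 31, 30))
  w <- data.frame(start = 1L, end = 101L)
  fv <- pm_window_features(rec, w[1, ], peaks = list(), sensors = character(0))
  expect_equal(fv[["temp_ratio_temple_finger"]], 1.1)
  expect_equal(fv[["temp_diff_temple_finger"]], 3.0)
  expect_equal(fv[["temp_ratio_forehead_finger"]], 1.1)
  expect_equal(fv[["temp_diff_forehead_finger"]], 3.0)

  rec2 <- make_recording(duration_s = 30, fs = 10, temp_value = 32)
  fv2 <- pm_window_features(rec2, w[1, ], peaks = list(),
                            sensors = character(0))
  expect_equal(fv2[["temp_ratio_temple_finger"]], 1)
  expect_equal(fv2[["temp_diff_forehead_finger"]], 0)
})

test_that("temperature SD features appear only behind the opt-in flag", {
  rec <- make_recording(duration_s = 30, fs = 10)
  w <- data.frame(start = 1L, end = 101L)
  fv <- pm_window_features(rec, w[1, ], peaks = list(), sensors = character(0))
  expect_false(any(grepl("^temp_.*_sd$", names(fv))))
  fv2 <- pm_window_features(rec, w[1, ], peaks = list(),
                            sensors = character(0), temp_sd = TRUE)
  expect_true("temp_forehead_sd" %in% names(fv2))
})

test_that("half-recording labels follow the midpoint rule", {
  rec <- make_recording(duration_s = 600, fs = 1, pain = c(3L, 5L))
  w <- data.frame(start = c(116L, 476L), end = c(126L, 486L))
  lw <- pm_assign_pain_labels(w, rec)  # midpoints at 120 s and 480 s
  expect_identical(lw$label, c(3L, 5L))
  expect_identical(lw$half, c("first", "second"))

  same <- make_recording(duration_s = 600, fs = 1, pain = c(4L, 4L))
  expect_true(all(pm_assign_pain_labels(w, same)$label == 4L))

  # midpoint exactly at 300 s: second half by the half-open convention
  w300 <- data.frame(start = 296L, end = 306L)
  expect_identical(pm_assign_pain_labels(w300, rec)$half, "second")
  expect_identical(pm_assign_pain_labels(w300, rec)$label, 5L)
})

test_that("every labeled window carries one of its recording's two scores", {
  cfg <- pm_synth_config(duration_s = 60, seed = 17)
  gen <- pm_generate_recording(pain = c(2L, 9L), cfg = cfg, seed = 17)
  ft <- pm_recording_features(gen$recording, sensors = "temple")
  expect_true(all(ft$label %in% c(2L, 9L)))
})

test_that("windows lacking two complete pulses are dropped and counted", {
  cfg <- pm_synth_config(duration_s = 60, seed = 19, artifact_fraction = 0)
  gen <- pm_generate_recording(pain = c(5L, 5L), cfg = cfg, seed = 19)
  rec <- gen$recording
  prep <- pm_preprocess_recording(rec, sensors = "temple")
  # keep only one peak inside the first window: no complete pulse survives
  w1 <- prep$windows[1, ]
  doctored <- prep
  doctored$peaks$temple <- prep$peaks$temple[
    prep$peaks$temple >= w1$start & prep$peaks$temple < w1$start + 20 |
      prep$peaks$temple >= w1$end]
  ft <- pm_recording_features(rec, sensors = "temple", prep = doctored)
  expect_identical(attr(ft, "n_dropped"), 1L)
})

test_that("z-scoring is fit on train only and drops constant features", {
  train <- data.frame(recording_id = "a", subject_id = "s", half = "first",
                      label = 1:6,
                      f1 = c(1, 2, 3, 4, 5, 6), f2 = rep(7, 6))
  test <- train
  test$f1 <- c(3.5, 0, 1, 2, 3, 4)
  z <- pm_fit_apply_zscore(train, test)
  expect_false("f2" %in% names(z$train))
  expect_false("f2" %in% names(z$test))
  expect_identical(z$dropped, "f2")
  expect_equal(mean(z$train$f1), 0)
  expect_equal(sd(z$train$f1), 1)
  expect_equal(z$test$f1[1], 0)  # equals the train mean
  expect_error(pm_fit_apply_zscore(train[0, ]), "empty")
})
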