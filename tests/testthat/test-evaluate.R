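test_that("pearson r matches closed forms and guards degenerate input", {
  obs <- c(1, 3, 4, 6, 8)
  expect_equal(pm_pearson_r(obs, obs), 1.0)
  expect_equal(pm_pearson_r(-obs + 7, obs), -1.0)
  pred <- c(2, 2.5, 5, 5.5, 7)
  # textbook product-moment formula, written out independently
  num <- sum((pred - mean(pred)) * (obs - mean(obs)))
  den <- sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
  expect_equal(pm_pearson_r(pred, obs), num / den, tolerance = 1e-12)
  expect_error(pm_pearson_r(rep(1, 5), obs), "constant")
  expect_error(pm_pearson_r(1, 1), "2 points")
})

test_that("rmse matches arithmetic cases", {
  expect_equal(pm_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pm_rmse(c(3, 4, 5), c(1, 2, 3)), 2)
  expect_equal(pm_rmse(c(0, 0), c(1, -1)), 1)
  expect_error(pm_rmse(numeric(0), numeric(0)), "empty")
})

test_that("ICC(3,1) matches an independent ANOVA oracle and is shift-invariant", {
  obs <- c(2, 4, 5, 7, 8, 3)
  expect_equal(pm_icc31(obs, obs), 1.0)
  expect_equal(pm_icc31(obs + 2.5, obs), 1.0)
  set.seed(44)
  for (k in 1:5) {
    o <- rnorm(6)
    p <- 0.6 * o + rnorm(6, 0, 0.5)
    expect_equal(pm_icc31(p, o), oracle_icc31(p, o), tolerance = 1e-10)
  }
  expect_error(pm_icc31(c(1, 1), c(1, 1)), "undefined")
})

test_that("Bland-Altman bias and limits match hand computation", {
  obs <- c(1, 2, 3, 4)
  ba0 <- pm_bland_altman(obs, obs)
  expect_equal(c(ba0$bias, ba0$lower, ba0$upper), c(0, 0, 0))
  ba1 <- pm_bland_altman(obs + 1, obs)
  expect_equal(c(ba1$bias, ba1$lower, ba1$upper), c(1, 1, 1))

  pred <- c(1.5, 1.8, 3.4, 4.9)
  d <- pred - obs  # 0.5, -0.2, 0.4, 0.9
  m <- sum(d) / 4
  s <- sqrt(sum((d - m)^2) / 3)
  ba <- pm_bland_altman(pred, obs)
  expect_equal(ba$bias, m, tolerance = 1e-12)
  expect_equal(ba$lower, m - 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$upper, m + 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$x, obs)
  expect_equal(ba$upper - ba$bias, ba$bias - ba$lower)
  expect_error(pm_bland_altman(1, 1), "2 points")
})

test_that("leave-one-recording-out predicts each window once, by its own fold", {
  ft <- make_feature_table(n_recordings = 5, windows_per_rec = 6,
                           noise_sd = 0.2, seed = 21)
  spec <- pm_model_spec("population", "temple", num_trees = 60, seed = 9)
  cv <- pm_loro_cv(ft, spec)
  expect_identical(nrow(cv), nrow(ft))
  expect_false(anyNA(cv$predicted))
  expect_identical(cv$fold, cv$recording_id)
  expect_identical(cv$recording_id, ft$recording_id)
  expect_error(pm_loro_cv(ft[ft$recording_id == "r01", ], spec),
               "at least 2")

  # two recordings: each predicted by a model trained solely on the other
  two <- ft[ft$recording_id %in% c("r01", "r02"), ]
  cv2 <- pm_loro_cv(two, spec)
  expect_identical(sort(unique(cv2$fold)), c("r01", "r02"))
})

test_that("held-out labels never leak into a fold's predictions", {
  ft <- make_feature_table(n_recordings = 5, windows_per_rec = 6,
                           noise_sd = 0.2, seed = 22)
  spec <- pm_model_spec("population", "temple", num_trees = 60, seed = 9)
  cv <- pm_loro_cv(ft, spec)
  # wreck the labels of one held-out recording: its predictions (and only
  # the *other* recordings' training sets) would notice a leak
  wrecked <- ft
  wrecked$label[wrecked$recording_id == "r03"] <- 999
  cv2 <- pm_loro_cv(wrecked, spec)
  sel <- cv$recording_id == "r03"
  expect_identical(cv$predicted[sel], cv2$predicted[sel])

  # provenance columns are not part of the feature schema, and recording
  # identity enters only through fold structure: renaming recordings with a
  # bijection leaves every prediction unchanged
  expect_false(any(c("recording_id", "subject_id", "half", "label") %in%
                     pm_feature_cols(ft)))
  renamed <- ft
  renamed$recording_id <- paste0("zz_", renamed$recording_id)
  cv3 <- pm_loro_cv(renamed, spec)
  expect_identical(cv3$predicted, cv$predicted)
})

test_that("permutation p-values are smoothed, bounded, and reproducible", {
  ft <- make_feature_table(n_recordings = 6, windows_per_rec = 6,
                           noise_sd = 0.1, seed = 30)
  spec <- pm_model_spec("population", "temple", num_trees = 60, seed = 2)
  pt <- pm_permutation_test(ft, spec, n_perm = 19, seed = 7)
  expect_gt(pt$p, 0)
  expect_lte(pt$p, 1)
  # strong linear signal: the observed r beats every shuffled refit
  expect_equal(pt$p, 1 / 20)
  pt2 <- pm_permutation_test(ft, spec, n_perm = 19, seed = 7)
  expect_identical(pt$null_r, pt2$null_r)
  pt3 <- pm_permutation_test(ft, spec, n_perm = 19, seed = 8)
  expect_false(identical(pt$null_r, pt3$null_r))
  expect_error(pm_permutation_test(ft, spec, n_perm = 0), "n_perm")
})

test_that("the evaluation report assembles all metrics coherently", {
  ft <- make_feature_table(n_recordings = 5, windows_per_rec = 8,
                           noise_sd = 0.3, seed = 33)
  spec <- pm_model_spec("population", "temple", num_trees = 80, seed = 4)
  rep_ <- pm_evaluate(ft, spec, n_perm = 9, seed = 1)
  expect_s3_class(rep_, "pm_eval_report")
  expect_true(rep_$r >= -1 && rep_$r <= 1)
  expect_gte(rep_$rmse, 0)
  expect_gt(rep_$perm_p, 0)
  expect_equal(rep_$ba_upper - rep_$ba_bias, rep_$ba_bias - rep_$ba_lower,
               tolerance = 1e-12)
  expect_identical(rep_$n_windows, 40L)
  expect_identical(rep_$n_recordings, 5L)
  expect_output(print(rep_), "ICC")
})
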