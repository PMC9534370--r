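# Evaluation harness: leave-one-recording-out cross-validation, Pearson r,
# RMSE, ICC(3,1), recording-level permutation null, Bland-Altman agreement.

#' Pearson correlation between predicted and observed scores
#' @param pred,obs numeric vectors of equal length >= 2; neither constant.
#' @return the product-moment correlation.
#' @export
pm_pearson_r <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(pred, obs)
}

#' Root mean square error
#' @param pred,obs numeric vectors of equal length >= 1.
#' @return `sqrt(mean((pred - obs)^2))`, in pain-score units.
#' @export
pm_rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  if (!length(pred)) stop("empty input", call. = FALSE)
  sqrt(mean((pred - obs)^2))
}

#' Intraclass correlation ICC(3,1)
#'
#' Shrout-Fleiss two-way mixed-model, single-measure, consistency
#' coefficient: windows are the targets, \{reported, predicted\} the k = 2
#' fixed raters; `ICC = (MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)`
#' with mean squares from the two-way ANOVA decomposition. Consistency form:
#' invariant to a constant shift of one rater.
#'
#' @param pred,obs paired numeric vectors, length >= 2.
#' @return the ICC(3,1) value.
#' @export
pm_icc31 <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  n <- length(pred)
  if (n < 2L) stop("need at least 2 paired observations", call. = FALSE)
  x <- cbind(obs, pred)
  k <- 2L
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows + (k - 1) * ms_err == 0) {
    stop("ICC undefined: no between-target variance", call. = FALSE)
  }
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

#' Bland-Altman agreement between predicted and reported scores
#'
#' Differences are predicted minus reported; the bias is their mean and the
#' limits of agreement are bias +/- 1.96 SD. For plotting, the x-axis is
#' the reported (reference) score rather than the pairwise mean.
#'
#' @param pred,obs numeric vectors of equal length >= 2.
#' @return list with `bias`, `lower`, `upper`, `sd`, and the per-point
#'   `differences` plus `x` (reported scores).
#' @export
pm_bland_altman <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 2L) stop("need at least 2 points", call. = FALSE)
  d <- pred - obs
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       sd = s, differences = d, x = obs)
}

# Precompute the leave-one-recording-out folds once: per held-out
# recording, row indices and the fold-normalized feature blocks (z-scoring
# is label-independent, so folds can be reused across label permutations).
pm_loro_folds <- function(features, spec) {
  recs <- unique(features$recording_id)
  if (length(recs) < 2L) {
    stop("leave-one-recording-out needs at least 2 recordings",
         call. = FALSE)
  }
  if (spec$level == "individual" &&
      length(unique(features$subject_id)) > 1L) {
    stop("individual-level models require a single subject's data",
         call. = FALSE)
  }
  lapply(recs, function(rid) {
    test_idx <- which(features$recording_id == rid)
    train_idx <- which(features$recording_id != rid)
    z <- pm_fit_apply_zscore(features[train_idx, , drop = FALSE],
                             features[test_idx, , drop = FALSE])
    cols <- pm_feature_cols(z$train)
    list(recording_id = rid, train_idx = train_idx, test_idx = test_idx,
         ztrain = z$train[cols], ztest = z$test[cols],
         mtrain = as.matrix(z$train[cols]), mtest = as.matrix(z$test[cols]))
  })
}

# Fit-and-predict one fold for a given label vector (full-table order).
pm_fold_predict <- function(fold, labels, spec, fold_seed) {
  ytrain <- labels[fold$train_idx]
  if (spec$level == "population") {
    mtry <- max(1L, floor(spec$mtry_fraction * ncol(fold$mtrain)))
    forest <- ranger::ranger(
      x = fold$mtrain, y = ytrain,
      num.trees = spec$num_trees, mtry = mtry,
      min.node.size = spec$min_node_size,
      max.depth = if (spec$max_depth > 0) spec$max_depth else NULL,
      replace = spec$bootstrap, num.threads = 1L, seed = fold_seed,
      verbose = FALSE)
    stats::predict(forest, data = fold$mtest, num.threads = 1L,
                   verbose = FALSE)$predictions
  } else {
    dat <- cbind(data.frame(label = ytrain), fold$ztrain)
    model <- pm_fit_individual(dat, spec)
    predict(model, fold$ztest)
  }
}

#' Leave-one-recording-out cross-validation
#'
#' All windows of one recording are held out together; the model (and the
#' z-score normalization) is refit on the remaining recordings and the
#' held-out windows are predicted. Every window is predicted exactly once,
#' by a model that never saw any window of its recording.
#'
#' @param features labeled feature table (>= 2 recordings; one subject for
#'   individual-level specs).
#' @param spec a `pm_model_spec`.
#' @param folds optional precomputed folds from the internal fold builder
#'   (used to amortize normalization across permutations).
#' @param labels optional replacement label vector aligned with
#'   `features` rows (used by the permutation test).
#' @return data.frame: `recording_id`, `subject_id`, `half`, `observed`,
#'   `predicted`, `fold`.
#' @export
pm_loro_cv <- function(features, spec, folds = NULL, labels = NULL) {
  if (is.null(folds)) folds <- pm_loro_folds(features, spec)
  if (is.null(labels)) labels <- features$label
  pred <- rep(NA_real_, nrow(features))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    pred[fold$test_idx] <- pm_fold_predict(fold, labels, spec,
                                           fold_seed = spec$seed + f)
  }
  data.frame(recording_id = features$recording_id,
             subject_id = features$subject_id,
             half = features$half,
             observed = labels,
             predicted = pred,
             fold = features$recording_id,
             stringsAsFactors = FALSE)
}

# Recording-level (start, end) score pairs derived from a feature table;
# halves with no stable windows fall back to the other half's score.
pm_recording_scores <- function(features) {
  recs <- unique(features$recording_id)
  out <- data.frame(recording_id = recs,
                    pain_start = NA_real_, pain_end = NA_real_)
  for (i in seq_along(recs)) {
    rows <- features[features$recording_id == recs[i], ]
    p1 <- rows$label[rows$half == "first"]
    p2 <- rows$label[rows$half == "second"]
    out$pain_start[i] <- if (length(p1)) p1[1] else p2[1]
    out$pain_end[i] <- if (length(p2)) p2[1] else p1[1]
  }
  out
}

#' Recording-level permutation test of cross-validated performance
#'
#' The exchangeable unit is the recording: each recording's (start, end)
#' pain-score pair is moved as a pair to a uniformly random recording, the
#' full leave-one-recording-out pipeline is re-run on the shuffled labels,
#' and the cross-validated Pearson r is recorded. The p-value uses add-one
#' smoothing, `p = (1 + #\{null r >= observed r\}) / (n_perm + 1)`, so it is
#' never exactly zero.
#'
#' @param features labeled feature table.
#' @param spec a `pm_model_spec`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for the permutation draws.
#' @param scores optional data.frame (`recording_id`, `pain_start`,
#'   `pain_end`) giving the true score pairs; derived from the feature
#'   table when omitted.
#' @return list with `p`, `observed_r`, and the vector `null_r`.
#' @export
pm_permutation_test <- function(features, spec, n_perm = 1000L, seed = 1L,
                                scores = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (is.null(scores)) scores <- pm_recording_scores(features)
  scores <- scores[match(unique(features$recording_id),
                         scores$recording_id), ]
  folds <- pm_loro_folds(features, spec)
  cv <- pm_loro_cv(features, spec, folds = folds)
  observed_r <- pm_pearson_r(cv$predicted, cv$observed)
  rec_of_row <- match(features$recording_id, scores$recording_id)
  first_half <- features$half == "first"
  set.seed(seed)
  null_r <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(scores))
    p1 <- scores$pain_start[perm][rec_of_row]
    p2 <- scores$pain_end[perm][rec_of_row]
    lab <- ifelse(first_half, p1, p2)
    cvb <- pm_loro_cv(features, spec, folds = folds, labels = lab)
    null_r[b] <- if (stats::sd(cvb$observed) == 0 ||
                     stats::sd(cvb$predicted) == 0) {
      0
    } else {
      stats::cor(cvb$predicted, cvb$observed)
    }
  }
  p <- (1 + sum(null_r >= observed_r)) / (n_perm + 1)
  list(p = p, observed_r = observed_r, null_r = null_r)
}

#' Full evaluation report for one model specification
#'
#' Runs leave-one-recording-out cross-validation and computes the
#' evaluation battery: Pearson r, RMSE, ICC(3,1), Bland-Altman bias and
#' limits of agreement, and (optionally) the recording-level permutation
#' p-value.
#'
#' @param features labeled feature table.
#' @param spec a `pm_model_spec`.
#' @param n_perm permutations for the null (0 = skip the permutation test).
#' @param seed seed for the permutation draws.
#' @param scores optional recording-level score pairs (see
#'   [pm_permutation_test()]).
#' @return a `pm_eval_report` list: `r`, `rmse`, `icc31`, `perm_p`,
#'   `ba_bias`, `ba_lower`, `ba_upper`, `n_windows`, `n_recordings`, and
#'   the `predictions` data.frame.
#' @export
pm_evaluate <- function(features, spec, n_perm = 0L, seed = 1L,
                        scores = NULL) {
  cv <- pm_loro_cv(features, spec)
  ba <- pm_bland_altman(cv$predicted, cv$observed)
  report <- list(
    r = pm_pearson_r(cv$predicted, cv$observed),
    rmse = pm_rmse(cv$predicted, cv$observed),
    icc31 = pm_icc31(cv$predicted, cv$observed),
    perm_p = NA_real_,
    ba_bias = ba$bias, ba_lower = ba$lower, ba_upper = ba$upper,
    n_windows = nrow(cv),
    n_recordings = length(unique(cv$recording_id)),
    predictions = cv)
  if (n_perm > 0L) {
    pt <- pm_permutation_test(features, spec, n_perm = n_perm, seed = seed,
                              scores = scores)
    report$perm_p <- pt$p
    report$null_r <- pt$null_r
  }
  class(report) <- "pm_eval_report"
  report
}

#' @export
print.pm_eval_report <- function(x, ...) {
  cat(sprintf(
    "<pm_eval_report> %d windows / %d recordings\n  r = %.3f, RMSE = %.3f, ICC(3,1) = %.3f\n  Bland-Altman bias %.3f, limits [%.3f, %.3f]%s\n",
    x$n_windows, x$n_recordings, x$r, x$rmse, x$icc31,
    x$ba_bias, x$ba_lower, x$ba_upper,
    if (is.na(x$perm_p)) "" else sprintf(", perm p = %.4f", x$perm_p)))
  invisible(x)
}
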