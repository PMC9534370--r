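# The two predictive frameworks: per-subject recursive feature elimination
# down to 5 features + linear regression, and a pooled random-forest
# regression, each per pulse-sensor combination.

#' Model specification
#'
#' @param level `"individual"` (per-subject RFE + linear model) or
#'   `"population"` (pooled random forest).
#' @param sensors non-empty pulse-sensor combination.
#' @param n_selected number of features kept by RFE (individual level).
#' @param num_trees,mtry_fraction,min_node_size,max_depth,bootstrap forest
#'   hyperparameters (population level): tree count, per-split feature
#'   fraction, minimum node size, depth cap (`0` = unlimited), bootstrap
#'   resampling flag.
#' @param seed integer seed for the forest.
#' @return a `pm_model_spec` list.
#' @export
pm_model_spec <- function(level = c("population", "individual"),
                          sensors = "temple", n_selected = 5L,
                          num_trees = 500L, mtry_fraction = 1 / 3,
                          min_node_size = 5L, max_depth = 0L,
                          bootstrap = TRUE, seed = 1L) {
  level <- match.arg(level)
  if (!length(sensors)) stop("sensor combination must be non-empty",
                             call. = FALSE)
  stopifnot(all(sensors %in% PM_PULSE_SENSORS))
  structure(list(level = level, sensors = sensors,
                 n_selected = as.integer(n_selected),
                 num_trees = as.integer(num_trees),
                 mtry_fraction = mtry_fraction,
                 min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth),
                 bootstrap = isTRUE(bootstrap),
                 seed = as.integer(seed)),
            class = "pm_model_spec")
}

#' All pulse-sensor combinations in canonical order
#'
#' The seven non-empty subsets of \{temple, carotid, finger\}, ordered by
#' size then by sensor code, matching the conventional tabulation
#' (1; 2; 3; 1,2; 1,3; 2,3; 1,2,3).
#'
#' @param sensors available sensors (default all three).
#' @return list of character vectors.
#' @export
pm_sensor_combinations <- function(sensors = PM_PULSE_SENSORS) {
  out <- list()
  for (k in seq_along(sensors)) {
    cmb <- utils::combn(sensors, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Recursive feature elimination with a linear base model
#'
#' Repeatedly fits a least-squares linear model on the current feature set
#' (columns standardized internally so the ranking is scale-fair), ranks
#' features by absolute standardized coefficient, and removes exactly one
#' least-important feature per iteration until `n_keep` survive. Aliased
#' (collinear) and zero-variance features rank lowest; importance ties are
#' broken by removing the feature latest in canonical (input column) order,
#' so the earlier-named duplicate survives. Deterministic.
#'
#' @param x data.frame or matrix of candidate features.
#' @param y numeric response (must not be constant).
#' @param n_keep number of features to retain (`1 <= n_keep <= ncol(x)`).
#' @return character vector of the surviving feature names, in canonical
#'   order.
#' @export
pm_rfe_select <- function(x, y, n_keep = 5L) {
  x <- as.data.frame(x)
  if (n_keep < 1L) stop("n_keep must be >= 1", call. = FALSE)
  if (ncol(x) < n_keep) {
    stop("fewer features (", ncol(x), ") than n_keep (", n_keep, ")",
         call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("response is constant; feature ranking undefined", call. = FALSE)
  }
  canonical <- names(x)
  current <- canonical
  while (length(current) > n_keep) {
    xm <- as.matrix(x[current])
    mu <- colMeans(xm)
    sdev <- apply(xm, 2, stats::sd)
    ok <- is.finite(sdev) & sdev > 0
    xs <- sweep(xm, 2, mu, "-")
    xs[, ok] <- sweep(xs[, ok, drop = FALSE], 2, sdev[ok], "/")
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xs), y)
    beta <- fit$coefficients[-1]
    importance <- abs(beta)
    importance[!is.finite(importance)] <- 0
    importance[!ok] <- 0
    worst <- which(importance == min(importance))
    drop_name <- current[max(worst)]  # latest canonical name among ties
    current <- setdiff(current, drop_name)
  }
  canonical[canonical %in% current]
}

#' Fit the per-subject linear model after RFE
#'
#' @param features feature table of one subject's windows (with `label`).
#' @param spec a `pm_model_spec` with `level = "individual"`.
#' @return a `pm_model` with the selected feature names and coefficients.
#' @export
pm_fit_individual <- function(features, spec) {
  stopifnot(inherits(spec, "pm_model_spec"))
  y <- features$label
  if (length(unique(y)) < 2L) {
    stop("subject has fewer than 2 distinct pain labels", call. = FALSE)
  }
  cols <- pm_feature_cols(features)
  selected <- pm_rfe_select(features[cols], y, spec$n_selected)
  dat <- features[c("label", selected)]
  fit <- stats::lm(label ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear feature(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  structure(list(spec = spec, selected = selected, fit = fit,
                 coefficients = cf),
            class = c("pm_model_individual", "pm_model"))
}

#' Fit the pooled population random forest
#'
#' A forest of regression trees, each grown on a bootstrap sample with a
#' random subset of features considered at every split; the prediction is
#' the mean over trees, so it always lies within the training label range.
#' Deterministic given `spec$seed`.
#'
#' @param features pooled feature table (windows stable for every sensor in
#'   the combination), with `label`.
#' @param spec a `pm_model_spec` with `level = "population"`.
#' @return a `pm_model` wrapping the fitted forest.
#' @export
pm_fit_population <- function(features, spec) {
  stopifnot(inherits(spec, "pm_model_spec"))
  if (!nrow(features)) {
    stop("no jointly stable windows: empty pooled feature table",
         call. = FALSE)
  }
  cols <- pm_feature_cols(features)
  x <- as.matrix(features[cols])
  y <- features$label
  mtry <- max(1L, floor(spec$mtry_fraction * ncol(x)))
  forest <- ranger::ranger(
    x = x, y = y,
    num.trees = spec$num_trees, mtry = mtry,
    min.node.size = spec$min_node_size,
    max.depth = if (spec$max_depth > 0) spec$max_depth else NULL,
    replace = spec$bootstrap,
    num.threads = 1L, seed = spec$seed, verbose = FALSE)
  structure(list(spec = spec, selected = cols, forest = forest,
                 train_range = range(y)),
            class = c("pm_model_population", "pm_model"))
}

#' Fit a model according to its specification
#' @param features labeled feature table.
#' @param spec a `pm_model_spec`.
#' @return a `pm_model`.
#' @export
pm_fit <- function(features, spec) {
  if (spec$level == "individual") pm_fit_individual(features, spec)
  else pm_fit_population(features, spec)
}

pm_check_model_cols <- function(model, newdata) {
  missing <- setdiff(model$selected, names(newdata))
  if (length(missing)) {
    stop("prediction input missing feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' @export
predict.pm_model_individual <- function(object, newdata, ...) {
  if (!nrow(newdata)) return(numeric(0))
  pm_check_model_cols(object, newdata)
  unname(stats::predict(object$fit, newdata = newdata[object$selected]))
}

#' @export
predict.pm_model_population <- function(object, newdata, ...) {
  if (!nrow(newdata)) return(numeric(0))
  pm_check_model_cols(object, newdata)
  x <- as.matrix(newdata[object$selected])
  stats::predict(object$forest, data = x, num.threads = 1L,
                 verbose = FALSE)$predictions
}
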