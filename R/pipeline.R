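# Orchestration: simulate -> preprocess -> features -> fit -> evaluate,
# with per-stage counts, provenance hashes, and deterministic reruns.

#' Pipeline configuration
#'
#' @param synth a [pm_synth_config()] to simulate a cohort, or `NULL` when
#'   reading an existing cohort from `manifest`.
#' @param manifest path to a cohort manifest TSV (ignored when `synth` is
#'   given).
#' @param combinations list of pulse-sensor combinations to run (default:
#'   all seven).
#' @param window_s analysis window length in seconds.
#' @param temp_sd include per-window temperature SD features.
#' @param n_selected features kept by RFE in the individual models.
#' @param num_trees,mtry_fraction,min_node_size,max_depth population-forest
#'   hyperparameters.
#' @param n_perm permutations for the population null (0 = skip).
#' @param seed master seed.
#' @return a `pm_pipeline_config` list.
#' @export
pm_pipeline_config <- function(synth = NULL, manifest = NULL,
                               combinations = pm_sensor_combinations(),
                               window_s = 10, temp_sd = FALSE,
                               n_selected = 5L, num_trees = 500L,
                               mtry_fraction = 1 / 3, min_node_size = 5L,
                               max_depth = 0L, n_perm = 0L, seed = 1L) {
  if (is.null(synth) && is.null(manifest)) {
    stop("provide either a synth config or a manifest path", call. = FALSE)
  }
  structure(list(synth = synth, manifest = manifest,
                 combinations = combinations, window_s = window_s,
                 temp_sd = temp_sd, n_selected = as.integer(n_selected),
                 num_trees = as.integer(num_trees),
                 mtry_fraction = mtry_fraction,
                 min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "pm_pipeline_config")
}

# Stability classification for every pulse channel of one recording.
pm_preprocess_channels <- function(rec) {
  n <- pm_n_samples(rec)
  peaks <- list()
  segments <- list()
  for (s in PM_PULSE_SENSORS) {
    pk <- pm_detect_peaks(rec$pulse[[s]], rec$fs)
    peaks[[s]] <- pk
    segments[[s]] <- suppressWarnings(pm_classify_stability(pk, n, rec$fs))
  }
  list(peaks = peaks, segments = segments)
}

# Features of one recording for one sensor combination, given the
# per-channel preprocessing.
pm_features_for_combination <- function(rec, chans, prep, window_s = 10,
                                        temp_sd = FALSE) {
  spans <- pm_remove_unstable(prep$segments, chans)
  windows <- pm_split_samples(spans, rec$fs, window_s)
  windows <- pm_assign_pain_labels(windows, rec)
  pm_recording_features(
    rec, sensors = chans, temp_sd = temp_sd,
    prep = list(peaks = prep$peaks, windows = windows))
}

#' Simulate a cohort and extract per-combination feature tables
#'
#' Streams recording by recording (generate, preprocess, featurize,
#' discard), so cohorts far larger than memory-resident signal storage can
#' be processed. Each pulse channel is peak-detected and
#' stability-classified once; every requested sensor combination then
#' intersects the stable spans and windows them.
#'
#' @param cfg a [pm_synth_config()].
#' @param combinations list of sensor combinations.
#' @param window_s window length in seconds.
#' @param temp_sd include temperature SD features.
#' @return list with `features` (named list of feature tables, one per
#'   combination, named by sensors joined with `+`), `scores`
#'   (recording-level pain pairs), and `stable_s` (per-recording stable
#'   seconds per channel).
#' @export
pm_simulate_features <- function(cfg, combinations = pm_sensor_combinations(),
                                 window_s = 10, temp_sd = FALSE) {
  cp <- pm_cohort_plan(cfg)
  plan <- cp$plan
  combo_names <- vapply(combinations, paste, character(1), collapse = "+")
  acc <- stats::setNames(vector("list", length(combinations)), combo_names)
  stable_rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    gen <- pm_generate_recording(
      subject = cp$subjects[[row$subject_idx]],
      pain = c(row$pain_start, row$pain_end),
      cfg = cfg, seed = row$rec_seed, recording_id = row$recording_id)
    rec <- gen$recording
    prep <- pm_preprocess_channels(rec)
    stable_rows[[i]] <- data.frame(
      recording_id = rec$recording_id,
      channel = PM_PULSE_SENSORS,
      stable_s = vapply(PM_PULSE_SENSORS, function(s) {
        sg <- prep$segments[[s]]
        sum((sg$end - sg$start)[sg$stable]) / rec$fs
      }, numeric(1)), row.names = NULL)
    for (ci in seq_along(combinations)) {
      ft <- pm_features_for_combination(rec, combinations[[ci]], prep,
                                        window_s, temp_sd)
      if (nrow(ft)) acc[[ci]] <- c(acc[[ci]], list(ft))
    }
  }
  features <- lapply(acc, function(lst) {
    if (length(lst)) do.call(rbind, lst) else NULL
  })
  scores <- data.frame(recording_id = plan$recording_id,
                       subject_id = plan$subject_id,
                       pain_start = plan$pain_start,
                       pain_end = plan$pain_end,
                       stringsAsFactors = FALSE)
  list(features = features, scores = scores,
       stable_s = do.call(rbind, stable_rows))
}

#' Extract per-combination feature tables from an on-disk cohort
#'
#' @param manifest_path cohort manifest TSV.
#' @param combinations list of sensor combinations.
#' @param window_s window length in seconds.
#' @param temp_sd include temperature SD features.
#' @return as [pm_simulate_features()], without ground-truth scores beyond
#'   those in the recordings themselves.
#' @export
pm_cohort_features <- function(manifest_path,
                               combinations = pm_sensor_combinations(),
                               window_s = 10, temp_sd = FALSE) {
  manifest <- pm_read_manifest(manifest_path)
  combo_names <- vapply(combinations, paste, character(1), collapse = "+")
  acc <- stats::setNames(vector("list", length(combinations)), combo_names)
  scores <- NULL
  for (i in seq_len(nrow(manifest))) {
    rec <- pm_read_recording(manifest$path[i])
    prep <- pm_preprocess_channels(rec)
    for (ci in seq_along(combinations)) {
      ft <- pm_features_for_combination(rec, combinations[[ci]], prep,
                                        window_s, temp_sd)
      if (nrow(ft)) acc[[ci]] <- c(acc[[ci]], list(ft))
    }
    scores <- rbind(scores, data.frame(
      recording_id = rec$recording_id, subject_id = rec$subject_id,
      pain_start = rec$pain_start, pain_end = rec$pain_end,
      stringsAsFactors = FALSE))
  }
  features <- lapply(acc, function(lst) {
    if (length(lst)) do.call(rbind, lst) else NULL
  })
  list(features = features, scores = scores, stable_s = NULL)
}

#' Run the full pipeline
#'
#' Simulates (or loads) a cohort, extracts features for every configured
#' sensor combination, evaluates the pooled population model per
#' combination (leave-one-recording-out), fits combination-selected
#' per-subject individual models, and writes all stage outputs plus a log
#' and a provenance file (stage -> output -> md5) under `out_dir`. Rerunning
#' with the same config and seed reproduces identical tables.
#'
#' @param config a [pm_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `metrics` (one row per combination, mirroring the
#'   per-combination results table layout), `individual` (per-subject best
#'   combination and r), `features`, and `out_dir`; all also written as
#'   TSVs.
#' @export
pm_run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pm_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  logf("pipeline start: seed %d, %d combination(s)", config$seed,
       length(config$combinations))

  if (!is.null(config$synth)) {
    ext <- pm_simulate_features(config$synth, config$combinations,
                                config$window_s, config$temp_sd)
  } else {
    ext <- pm_cohort_features(config$manifest, config$combinations,
                              config$window_s, config$temp_sd)
  }
  combo_names <- names(ext$features)

  metrics <- NULL
  for (ci in seq_along(combo_names)) {
    ft <- ext$features[[ci]]
    if (is.null(ft) || length(unique(ft$recording_id)) < 2L) {
      logf("combination %s: insufficient stable windows, skipped",
           combo_names[ci])
      metrics <- rbind(metrics, data.frame(
        combination = combo_names[ci], n_recordings = 0L, n_windows = 0L,
        r = NA_real_, rmse = NA_real_, icc31 = NA_real_, perm_p = NA_real_,
        ba_bias = NA_real_, ba_lower = NA_real_, ba_upper = NA_real_))
      next
    }
    spec <- pm_model_spec(
      level = "population", sensors = config$combinations[[ci]],
      num_trees = config$num_trees, mtry_fraction = config$mtry_fraction,
      min_node_size = config$min_node_size, max_depth = config$max_depth,
      seed = config$seed)
    rep_ <- pm_evaluate(ft, spec, n_perm = config$n_perm,
                        seed = config$seed, scores = ext$scores)
    data.table::fwrite(rep_$predictions,
                       file.path(out_dir, paste0("predictions_",
                                                 gsub("\\+", "_", combo_names[ci]),
                                                 ".tsv")),
                       sep = "\t", eol = "\n")
    metrics <- rbind(metrics, data.frame(
      combination = combo_names[ci],
      n_recordings = rep_$n_recordings, n_windows = rep_$n_windows,
      r = rep_$r, rmse = rep_$rmse, icc31 = rep_$icc31,
      perm_p = rep_$perm_p, ba_bias = rep_$ba_bias,
      ba_lower = rep_$ba_lower, ba_upper = rep_$ba_upper))
    logf("combination %s: %d windows, r=%.3f rmse=%.3f", combo_names[ci],
         rep_$n_windows, rep_$r, rep_$rmse)
  }

  individual <- pm_individual_models(ext$features, config)
  logf("individual models: %d subject(s)", nrow(individual))

  metrics_path <- file.path(out_dir, "metrics.tsv")
  data.table::fwrite(metrics, metrics_path, sep = "\t", eol = "\n")
  indiv_path <- file.path(out_dir, "individual.tsv")
  data.table::fwrite(individual, indiv_path, sep = "\t", eol = "\n")

  prov_files <- c(metrics_path, indiv_path)
  prov <- data.frame(file = basename(prov_files),
                     md5 = unname(tools::md5sum(prov_files)))
  data.table::fwrite(prov, file.path(out_dir, "provenance.tsv"),
                     sep = "\t", eol = "\n")
  logf("pipeline done")
  list(metrics = metrics, individual = individual, features = ext$features,
       out_dir = out_dir)
}

#' Combination-selected per-subject individual models
#'
#' For every subject, evaluates the RFE + linear model by
#' leave-one-recording-out cross-validation for every sensor combination
#' and reports the best combination by cross-validated r (selecting on
#' cross-validated performance is optimistic; the output is labeled
#' combination-selected accordingly).
#'
#' @param features_by_combo named list of feature tables per combination.
#' @param config a `pm_pipeline_config`.
#' @return data.frame: `subject_id`, `combination` (best), `r`, `rmse`,
#'   `icc31`, `n_windows`.
#' @export
pm_individual_models <- function(features_by_combo, config) {
  subjects <- sort(unique(unlist(lapply(features_by_combo, function(ft) {
    if (!is.null(ft)) unique(ft$subject_id)
  }))))
  out <- NULL
  for (sid in subjects) {
    best <- NULL
    for (ci in seq_along(features_by_combo)) {
      ft <- features_by_combo[[ci]]
      if (is.null(ft)) next
      fts <- ft[ft$subject_id == sid, , drop = FALSE]
      if (length(unique(fts$recording_id)) < 2L ||
          length(unique(fts$label)) < 2L) next
      spec <- pm_model_spec(level = "individual",
                            sensors = config$combinations[[ci]],
                            n_selected = config$n_selected,
                            seed = config$seed)
      res <- tryCatch({
        cv <- pm_loro_cv(fts, spec)
        if (stats::sd(cv$observed) == 0 || stats::sd(cv$predicted) == 0) {
          NULL
        } else {
          list(r = stats::cor(cv$predicted, cv$observed),
               rmse = pm_rmse(cv$predicted, cv$observed),
               icc31 = tryCatch(pm_icc31(cv$predicted, cv$observed),
                                error = function(e) NA_real_),
               n = nrow(cv),
               combo = names(features_by_combo)[ci])
        }
      }, error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$r > best$r)) best <- res
    }
    if (!is.null(best)) {
      out <- rbind(out, data.frame(
        subject_id = sid, combination = best$combo, r = best$r,
        rmse = best$rmse, icc31 = best$icc31, n_windows = best$n,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), combination = character(0),
                      r = numeric(0), rmse = numeric(0), icc31 = numeric(0),
                      n_windows = integer(0))
  }
  out
}

#' Summarize a completed pipeline run
#'
#' Renders the per-combination metrics and per-subject individual results
#' as text; optionally writes Bland-Altman and predicted-vs-reported plot
#' files (requires ggplot2).
#'
#' @param run_dir directory written by [pm_run_pipeline()].
#' @param plots write plot files under `run_dir/figures`.
#' @return the summary lines, invisibly; also printed.
#' @export
pm_report <- function(run_dir, plots = FALSE) {
  metrics_path <- file.path(run_dir, "metrics.tsv")
  indiv_path <- file.path(run_dir, "individual.tsv")
  missing <- c(metrics_path, indiv_path)[!file.exists(c(metrics_path,
                                                        indiv_path))]
  if (length(missing)) {
    stop("incomplete run; missing stage output(s): ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  metrics <- data.table::fread(metrics_path, data.table = FALSE)
  indiv <- data.table::fread(indiv_path, data.table = FALSE)
  lines <- c("Population models (leave-one-recording-out):")
  for (i in seq_len(nrow(metrics))) {
    m <- metrics[i, ]
    lines <- c(lines, if (m$n_windows == 0) {
      sprintf("  %-22s 0 windows", m$combination)
    } else {
      sprintf("  %-22s %4d rec %6d win  r=%.2f RMSE=%.2f ICC=%.2f",
              m$combination, m$n_recordings, m$n_windows, m$r, m$rmse,
              m$icc31)
    })
  }
  lines <- c(lines, "Individual models (combination-selected):")
  for (i in seq_len(nrow(indiv))) {
    s <- indiv[i, ]
    lines <- c(lines, sprintf("  %-6s best=%-22s r=%.2f RMSE=%.2f",
                              s$subject_id, s$combination, s$r, s$rmse))
  }
  if (plots) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      warning("ggplot2 not available; skipping plots")
    } else {
      fig_dir <- file.path(run_dir, "figures")
      dir.create(fig_dir, showWarnings = FALSE)
      pred_files <- list.files(run_dir, "^predictions_.*\\.tsv$",
                               full.names = TRUE)
      for (pf in pred_files) {
        cv <- data.table::fread(pf, data.table = FALSE)
        d <- cv$predicted - cv$observed
        ba <- ggplot2::ggplot(
          data.frame(x = cv$observed, d = d),
          ggplot2::aes(x = x, y = d)) +
          ggplot2::geom_point(alpha = 0.3) +
          ggplot2::geom_hline(yintercept = mean(d)) +
          ggplot2::geom_hline(yintercept = mean(d) + c(-1.96, 1.96) * sd(d),
                              linetype = "dashed") +
          ggplot2::labs(x = "Reported pain score",
                        y = "Predicted - reported")
        ggplot2::ggsave(file.path(
          fig_dir, sub("^predictions_(.*)\\.tsv$", "ba_\\1.png",
                       basename(pf))), ba, width = 5, height = 4, dpi = 120)
      }
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
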