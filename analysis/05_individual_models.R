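#!/usr/bin/env Rscript
# Per-subject linear models: recursive feature elimination down to 5
# features, then least squares, cross-validated leave-one-recording-out,
# reporting each subject's best sensor combination by cross-validated r.
# Found: with the generator's common coupling, most subjects are well
# predicted; with real heterogeneous physiology only a subset would be
# (combination selection on test performance is optimistic, and is labeled
# as such).

source("analysis/00_config.R")

files <- list.files(FEATURE_DIR, "^features_.*\\.tsv$", full.names = TRUE)
features_by_combo <- list()
combos <- list()
for (path in files) {
  nm <- gsub("_", "+", sub("^features_(.*)\\.tsv$", "\\1", basename(path)))
  features_by_combo[[nm]] <- data.table::fread(path, data.table = FALSE)
  combos[[length(combos) + 1L]] <- strsplit(nm, "+", fixed = TRUE)[[1]]
}
config <- pm_pipeline_config(synth = cohort_config(), combinations = combos,
                             n_selected = 5, seed = SEED)
indiv <- pm_individual_models(features_by_combo, config)
print(indiv, digits = 3, row.names = FALSE)
cat(sprintf("%d of %d subjects reach r >= 0.49\n",
            sum(indiv$r >= 0.49), nrow(indiv)))
data.table::fwrite(indiv, file.path(RESULTS_DIR, "individual_models.tsv"),
                   sep = "\t")
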