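# Shared configuration for the analysis scripts. Everything downstream of
# this file is deterministic given SEED.
#
# The demo cohort is smaller than a full field deployment (8 subjects x 6
# four-minute recordings rather than 12 x 15 ten-minute ones) so the whole
# analysis chain reruns in a few minutes on one CPU; the pipeline code
# itself is scale-free.

library(painmeter)

SEED <- 20260925L
COHORT_DIR <- "scratch/cohort"
FEATURE_DIR <- "scratch/features"
RESULTS_DIR <- "results"

cohort_config <- function() {
  pm_synth_config(
    n_subjects = 8,
    recordings_per_subject = 6,
    duration_s = 240,
    artifact_fraction = 0.10,      # realistic motion-artifact load
    artifact_mode = "noise_burst",
    seed = SEED)
}

population_spec <- function(sensors, seed = SEED) {
  pm_model_spec("population", sensors, num_trees = 200, min_node_size = 10,
                max_depth = 0L, seed = seed)
}

# Smaller forest for the 200-fold permutation refits; the null only needs
# the same pipeline shape, not the most accurate forest.
population_spec_perm <- function(sensors, seed = SEED) {
  pm_model_spec("population", sensors, num_trees = 30, min_node_size = 20,
                max_depth = 7L, seed = seed)
}

dir.create(RESULTS_DIR, showWarnings = FALSE)
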