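# Shared setup for the numbered analysis drivers: one master seed, one
# cohort specification (the study conditions), and a results directory.
# Each driver is independently runnable from the repository root:
#   Rscript analysis/01_simulate_cohort.R
suppressPackageStartupMessages(library(fractalbold))

MASTER_SEED <- 20230
RESULTS_DIR <- "results/analysis"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

study_spec <- function() cohort_spec(seed = MASTER_SEED)

# Cohort regenerated on demand (deterministic, ~10 s); maps via the PSD
# estimator used for the main analyses.
study_cohort <- function(keep_volumes = FALSE) {
  simulate_cohort(study_spec(), keep_volumes = keep_volumes,
                  map_fun = function(v) hurst_volume(v, "psd"))
}

save_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  path
}
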