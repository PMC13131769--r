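# Shared settings for the analysis scripts. A moderate cohort keeps every
# stage re-runnable in about a minute; the package tests and
# scripts/acceptance.R exercise the full-size conditions.

library(snqtl)

RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohort")
SEED <- 20260926L

analysis_config <- function() {
  sim_config(n_subjects = 200, n_datasets = 3, n_loci = 8,
             variants_per_locus = 25, genes_per_locus = 2,
             cells_per_subject_per_type = 10, seed = SEED)
}

dir.create(COHORT_DIR, showWarnings = FALSE, recursive = TRUE)
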