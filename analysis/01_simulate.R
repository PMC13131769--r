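#!/usr/bin/env Rscript
# Simulate the study cohort: three single-nucleus datasets over nine brain
# cell types, LD-structured genotypes at eight GWAS loci (half with a shared
# causal variant, a quarter with a linked causal variant, a quarter null),
# GWAS summary statistics, and phased allele counts. Everything is written
# through the package's readers/writers so later stages start from files.

source("analysis/00_config.R")

cfg <- analysis_config()
cohort <- simulate_cohort(cfg)

for (d in seq_along(cohort$datasets)) {
  ds <- cohort$datasets[[d]]
  tag <- sprintf("D%d", d)
  write_genotypes(ds$genotypes, file.path(COHORT_DIR, paste0(tag, "_dosages.tsv")))
  write_counts(ds$cells, file.path(COHORT_DIR, paste0(tag, "_counts")))
  write_table(ds$covariates, file.path(COHORT_DIR, paste0(tag, "_covariates.tsv")))
}
write_sumstats(cohort$gwas, file.path(COHORT_DIR, "gwas.tsv"))
write_table(cohort$ase, file.path(COHORT_DIR, "ase_counts.tsv"))
write_table(cohort$annotation, file.path(COHORT_DIR, "genes.tsv"))
write_table(cohort$panel, file.path(COHORT_DIR, "variants.tsv"))
write_table(cohort$truth$planted_eqtls, file.path(COHORT_DIR, "truth_eqtls.tsv"))
write_table(cohort$truth$gwas, file.path(COHORT_DIR, "truth_gwas.tsv"))

cat(sprintf(
  "Simulated %d datasets x %d subjects, %d cell types, %d variants, %d genes\n",
  cfg$n_datasets, cfg$n_subjects, length(cfg$cell_types),
  nrow(cohort$panel), nrow(cohort$annotation)))
cat(sprintf("Planted %d cis-eQTLs (effect %.2f on the log-mean scale); GWAS: %s\n",
            nrow(cohort$truth$planted_eqtls), cfg$eqtl_effect,
            paste(table(cfg$gwas_scenario), names(table(cfg$gwas_scenario)),
                  collapse = ", ")))
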