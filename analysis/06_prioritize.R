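#!/usr/bin/env Rscript
# Integrate the four tiers (eQTL significance, colocalization, SMR, HEIDI)
# with the evidence layers into the final risk-gene table and compare the
# prioritized set against the planted ground truth.

source("analysis/00_config.R")

meta <- read.delim(file.path(RESULTS, "meta_records.tsv"))
coloc <- read.delim(file.path(RESULTS, "coloc.tsv"))
smr <- read.delim(file.path(RESULTS, "smr.tsv"))
ase <- read.delim(file.path(RESULTS, "ase.tsv"))
dyn <- read.delim(file.path(RESULTS, "dynamic.tsv"))
bulk <- read.delim(file.path(RESULTS, "bulk_meta.tsv"))

tiers <- apply_four_tiers(meta, coloc, smr)
genes <- annotate_evidence(tiers, ase = ase, bulk_meta = bulk, dynamic = dyn)
write_table(tiers$by_cell_type, file.path(RESULTS, "tiers_by_cell_type.tsv"))
write_table(genes, file.path(RESULTS, "risk_genes.tsv"))

truth_gwas <- read.delim(file.path(COHORT_DIR, "truth_gwas.tsv"))
planted <- read.delim(file.path(COHORT_DIR, "truth_eqtls.tsv"))
shared <- planted$gene_id[planted$gene_id %in% sprintf(
  "gene_L%d_1", truth_gwas$locus[truth_gwas$scenario == "shared_causal"])]
linked_loci <- truth_gwas$locus[truth_gwas$scenario == "linked_causal"]
pri <- genes$gene_id[genes$prioritized]

cat(sprintf("Tier thresholds: eQTL %.3g (over %d pairs), SMR %.3g (over %d eGenes)\n",
            tiers$thresholds$tier1, tiers$thresholds$n_pairs,
            tiers$thresholds$tier3, tiers$thresholds$n_forwarded))
cat(sprintf("Prioritized genes: %s\n", paste(pri, collapse = ", ")))
cat(sprintf("Shared-causal recovery: %d / %d; linkage-locus genes prioritized: %d\n",
            sum(shared %in% pri), length(shared),
            sum(pri %in% unlist(lapply(linked_loci, function(l)
              sprintf("gene_L%d_%d", l, 1:2))))))
summ <- attr(genes, "summary")
cat(sprintf("Evidence among prioritized: ASE %d, bulk %d, dynamic %d\n",
            summ$n_ase, summ$n_bulk, summ$n_dynamic))
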