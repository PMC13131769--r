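#!/usr/bin/env Rscript
# Split the GWAS into independent LD chunks, colocalize every significant
# gene x cell type against the overlapping chunks, and run summary-based
# Mendelian randomization with the HEIDI linkage test using the top eSNP of
# each forwarded gene as the instrument.

source("analysis/00_config.R")

meta <- read.delim(file.path(RESULTS, "meta_records.tsv"))
gwas <- read_sumstats(file.path(COHORT_DIR, "gwas.tsv"))
panel <- read.delim(file.path(COHORT_DIR, "variants.tsv"))
ann <- read_gene_annotation(file.path(COHORT_DIR, "genes.tsv"))
gt <- read_genotypes(file.path(COHORT_DIR, "D1_dosages.tsv"))

n_pairs <- nrow(unique(meta[, c("gene_id", "variant_id")]))
thr1 <- bonferroni_threshold(0.05, n_pairs)$exact
sig <- unique(meta[meta$p_re2 <= thr1, c("gene_id", "cell_type")])

ld <- ld_r(gt)
gwas_clumps <- clump(gwas, ld, p1 = 5e-8, p2 = 5e-8)
gwas_chunks <- clump_spans(gwas_clumps, gwas)
write_table(gwas_chunks, file.path(RESULTS, "gwas_chunks.tsv"))
cat(sprintf("%d independent GWAS chunks\n", nrow(gwas_chunks)))

gwas_h <- harmonize_alleles(gwas, panel)
coloc <- pair_and_run(meta, sig, gwas_h, gwas_chunks, ann)
write_table(coloc, file.path(RESULTS, "coloc.tsv"))
cat(sprintf("coloc: %d gene-chunk pairs, %d with PP4 >= 0.8\n",
            nrow(coloc), sum(coloc$pass)))

smr <- run_smr(meta, sig, gwas_h, ld)
write_table(smr, file.path(RESULTS, "smr.tsv"))
thr3 <- bonferroni_threshold(0.05, length(unique(sig$gene_id)))$exact
cat(sprintf("SMR: %d tests, %d below the %.3g threshold, %d passing HEIDI (p >= 0.01)\n",
            nrow(smr), sum(pmin(smr$p_smr, smr$p_smr_multi) <= thr3), thr3,
            sum(!is.na(smr$p_heidi) & smr$p_heidi >= 0.01)))
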