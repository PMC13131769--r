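#!/usr/bin/env Rscript
# Combine the per-dataset eQTL statistics with fixed-effects, DerSimonian-
# Laird random-effects, and Han-Eskin RE2 models; derive the Bonferroni
# threshold from the realized number of unique eSNP-eGene pairs; clump the
# significant eGenes into independent LD chunks; estimate cross-cell-type
# sharing with the pi1 statistic.

source("analysis/00_config.R")

eqtl <- read.delim(file.path(RESULTS, "eqtl_records.tsv"))
meta <- meta_analyze(split(eqtl, eqtl$dataset))
write_table(meta, file.path(RESULTS, "meta_records.tsv"))

n_pairs <- nrow(unique(meta[, c("gene_id", "variant_id")]))
thr <- bonferroni_threshold(0.05, n_pairs)
cat(sprintf("Bonferroni threshold over %d pairs: %.3g\n", n_pairs, thr$rounded))

sig <- meta[meta$p_re2 <= thr$exact, ]
cat(sprintf("%d significant records, %d eGenes, %d cell types\n",
            nrow(sig), length(unique(sig$gene_id)),
            length(unique(sig$cell_type))))

gt <- read_genotypes(file.path(COHORT_DIR, "D1_dosages.tsv"))
gwas <- read_sumstats(file.path(COHORT_DIR, "gwas.tsv"))
ld <- ld_r(gt)
chunks <- list()
for (g in unique(sig$gene_id)) {
  mr <- meta[meta$gene_id == g, ]
  pmin_v <- aggregate(p_re2 ~ variant_id, data = mr, FUN = min)
  st <- data.frame(snp = pmin_v$variant_id, p = pmin_v$p_re2,
                   chr = gwas$chr[match(pmin_v$variant_id, gwas$snp)],
                   bp = gwas$bp[match(pmin_v$variant_id, gwas$snp)])
  cl <- clump(st, ld, p1 = thr$exact, p2 = thr$exact)
  if (nrow(cl)) { cl$gene_id <- g; chunks[[g]] <- cl }
}
chunks <- do.call(rbind, chunks)
write_table(chunks, file.path(RESULTS, "eqtl_chunks.tsv"))
n_ind <- length(unique(paste(chunks$gene_id, chunks$chunk_id)))
cat(sprintf("%d independent eQTL chunks (%d primary + %d additional)\n",
            n_ind, length(unique(chunks$gene_id)),
            n_ind - length(unique(chunks$gene_id))))

# sharing: p-values of GLU-significant eSNPs in the other cell types
glu <- sig[sig$cell_type == "GLU", c("gene_id", "variant_id")]
if (nrow(glu)) {
  other <- merge(meta[meta$cell_type != "GLU", ], glu)
  cat(sprintf("pi1 of GLU eSNPs in other cell types: %.2f (%d tests)\n",
              pi1(pmin(pmax(other$p_re2, 1e-300), 1)), nrow(other)))
}
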