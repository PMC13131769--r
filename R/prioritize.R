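#' Bonferroni threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return list `exact` (`alpha/m`) and `rounded` (3 significant figures).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  exact <- alpha / m
  list(exact = exact, rounded = signif(exact, 3))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (`q_(i) = min_(j>=i) p_(j) m / j`, clipped at 1),
#' returned in input order. Thin wrapper over `stats::p.adjust`.
#'
#' @param pvalues p-values.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Apply the four-tier prioritization criteria
#'
#' Per gene x cell type: tier 1 — the meta RE2 p of some cis variant is at
#' or below the Bonferroni threshold over the realized number of unique
#' eSNP-eGene pairs; tier 2 — some paired GWAS chunk colocalizes
#' (PP4 >= `pp4_threshold`); tier 3 — the single- or multi-SNP SMR p is at
#' or below the Bonferroni threshold over the number of forwarded eGenes;
#' tier 4 — the HEIDI p is >= `heidi_alpha` (no evidence of linkage).
#' Genes with an absent HEIDI result are excluded by default
#' (`heidi_missing = "exclude"`). A gene is prioritized when all four
#' tiers pass in at least one cell type.
#'
#' @param meta_records meta records over all tested pairs.
#' @param coloc results from [pair_and_run()].
#' @param smr results from [run_smr()].
#' @param alpha family-wise rate for both Bonferroni thresholds (0.05).
#' @param pp4_threshold tier-2 posterior threshold (0.8).
#' @param heidi_alpha tier-4 pass threshold (0.01).
#' @param heidi_missing `"exclude"` (default) or `"pass"` for genes whose
#'   HEIDI test had too few candidate SNPs.
#' @return list: `by_cell_type` (gene x cell-type tier flags), `genes`
#'   (one row per tier-1 gene with `prioritized`, passing cell types, best
#'   eSNP), `thresholds` (`tier1`, `tier3`, `n_pairs`, `n_forwarded`).
#' @export
apply_four_tiers <- function(meta_records, coloc, smr, alpha = 0.05,
                             pp4_threshold = 0.8, heidi_alpha = 0.01,
                             heidi_missing = c("exclude", "pass")) {
  heidi_missing <- match.arg(heidi_missing)
  if (is.null(meta_records) || !nrow(meta_records))
    stop("four-tier integration: meta-analysis table is missing or empty")
  n_pairs <- nrow(unique(meta_records[, c("gene_id", "variant_id")]))
  thr1 <- bonferroni_threshold(alpha, n_pairs)$exact

  gct <- unique(meta_records[, c("gene_id", "cell_type")])
  gct$tier1_eqtl <- mapply(function(g, ct) {
    any(meta_records$p_re2[meta_records$gene_id == g &
                             meta_records$cell_type == ct] <= thr1)
  }, gct$gene_id, gct$cell_type)
  gct <- gct[gct$tier1_eqtl, , drop = FALSE]

  n_forwarded <- length(unique(gct$gene_id))
  thr3 <- if (n_forwarded > 0) bonferroni_threshold(alpha, n_forwarded)$exact
          else NA_real_

  flag <- function(df, cond) {
    if (is.null(df) || !nrow(df)) return(rep(FALSE, nrow(gct)))
    mapply(function(g, ct) {
      i <- df$gene_id == g & df$cell_type == ct
      any(cond(df[i, , drop = FALSE]))
    }, gct$gene_id, gct$cell_type)
  }
  gct$tier2_coloc <- flag(coloc, function(d) d$pp4 >= pp4_threshold)
  gct$tier3_smr <- flag(smr, function(d)
    pmin(d$p_smr, ifelse(is.na(d$p_smr_multi), Inf, d$p_smr_multi)) <= thr3)
  gct$tier4_heidi <- flag(smr, function(d) {
    h <- d$p_heidi
    if (heidi_missing == "pass") h[is.na(h)] <- 1
    !is.na(h) & h >= heidi_alpha
  })
  gct$all_four <- gct$tier1_eqtl & gct$tier2_coloc & gct$tier3_smr &
    gct$tier4_heidi

  genes <- data.frame(gene_id = unique(gct$gene_id), stringsAsFactors = FALSE)
  genes$cell_types <- vapply(genes$gene_id, function(g)
    paste(gct$cell_type[gct$gene_id == g & gct$all_four], collapse = ","),
    "")
  genes$prioritized <- genes$cell_types != ""
  genes$best_esnp <- vapply(genes$gene_id, function(g) {
    mr <- meta_records[meta_records$gene_id == g, , drop = FALSE]
    mr$variant_id[which.min(mr$p_re2)]
  }, "")
  rownames(gct) <- rownames(genes) <- NULL
  list(by_cell_type = gct, genes = genes,
       thresholds = list(tier1 = thr1, tier3 = thr3, n_pairs = n_pairs,
                         n_forwarded = n_forwarded))
}

#' Attach orthogonal evidence flags to prioritized genes
#'
#' ASE support: a matching allelic-imbalance test with p <= `ase_alpha`.
#' Bulk replication: a matching bulk meta record with BH q <= `bulk_fdr`.
#' Dynamic eQTL: a matching genotype x pathology interaction with
#' p <= `dynamic_alpha`. A gene absent from an evidence table gets `NA`
#' (insufficient data), never `FALSE`.
#'
#' @param tiers output of [apply_four_tiers()].
#' @param ase results from [ase_test_all()] (or `NULL`).
#' @param bulk_meta bulk meta records (or `NULL`); q-values are computed
#'   over all bulk records.
#' @param dynamic results from [dynamic_interaction()] (or `NULL`).
#' @param ase_alpha,bulk_fdr,dynamic_alpha thresholds (0.05, 0.05, 0.01).
#' @return `tiers$genes` with `ase_support`, `bulk_replicated`,
#'   `dynamic_eqtl` columns plus a `summary` attribute of tallies.
#' @export
annotate_evidence <- function(tiers, ase = NULL, bulk_meta = NULL,
                              dynamic = NULL, ase_alpha = 0.05,
                              bulk_fdr = 0.05, dynamic_alpha = 0.01) {
  genes <- tiers$genes
  ev <- function(df, gene, hit) {
    if (is.null(df) || !nrow(df)) return(NA)
    i <- df$gene_id == gene
    if (!any(i)) return(NA)
    any(hit(df[i, , drop = FALSE]))
  }
  if (!is.null(bulk_meta) && nrow(bulk_meta))
    bulk_meta$q <- bh_fdr(bulk_meta$p_re2)
  genes$ase_support <- vapply(genes$gene_id, function(g)
    ev(ase, g, function(d) d$p <= ase_alpha), NA)
  genes$bulk_replicated <- vapply(genes$gene_id, function(g)
    ev(bulk_meta, g, function(d) d$q <= bulk_fdr), NA)
  genes$dynamic_eqtl <- vapply(genes$gene_id, function(g)
    ev(dynamic, g, function(d) d$p_interaction <= dynamic_alpha), NA)
  pri <- genes[genes$prioritized, , drop = FALSE]
  attr(genes, "summary") <- list(
    n_prioritized = nrow(pri),
    n_with_evidence = sum(pri$ase_support | pri$bulk_replicated |
                            pri$dynamic_eqtl, na.rm = TRUE),
    n_ase = sum(pri$ase_support, na.rm = TRUE),
    n_bulk = sum(pri$bulk_replicated, na.rm = TRUE),
    n_dynamic = sum(pri$dynamic_eqtl, na.rm = TRUE))
  genes
}
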