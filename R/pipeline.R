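#' Run the full four-tier prioritization pipeline on a synthetic cohort
#'
#' Executes simulate -> pseudobulk -> covariate adjustment -> per-dataset
#' cis-eQTL mapping -> FE/RE/RE2 meta-analysis -> eQTL and GWAS LD
#' clumping -> colocalization -> SMR/HEIDI -> allelic imbalance -> dynamic
#' eQTLs -> bulk replication -> four-tier integration, and returns every
#' intermediate plus a Table-1-style report and a machine-readable run
#' manifest. Idempotent under a fixed config seed.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, the report, the per-stage
#'   tables and the manifest are written as TSV/JSON.
#' @param n_hidden surrogate factors for covariate adjustment (default 2;
#'   the synthetic gene panel is small, so few surrogates are identifiable).
#' @param min_cells per-subject cell floor (default 10).
#' @param alpha family-wise rate for the Bonferroni tiers (0.05).
#' @param pp4_threshold,heidi_alpha,ase_alpha,bulk_fdr,dynamic_alpha
#'   downstream thresholds (0.8, 0.01, 0.05, 0.05, 0.01).
#' @param bulk_n_subjects,bulk_n_datasets bulk replication cohorts
#'   (150 subjects x 2 by default; 0 datasets skips the stage).
#' @param heidi_missing policy for genes without a computable HEIDI test.
#' @return list with `cohort`, `eqtl` (per-dataset records), `meta`,
#'   `candidates`, `eqtl_chunks`, `gwas_chunks`, `coloc`, `smr`, `ase`,
#'   `concordance`, `dynamic`, `bulk_meta`, `tiers`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         n_hidden = 2, min_cells = 10, alpha = 0.05,
                         pp4_threshold = 0.8, heidi_alpha = 0.01,
                         ase_alpha = 0.05, bulk_fdr = 0.05,
                         dynamic_alpha = 0.01, bulk_n_subjects = 150,
                         bulk_n_datasets = 2,
                         heidi_missing = c("exclude", "pass")) {
  heidi_missing <- match.arg(heidi_missing)
  cohort <- simulate_cohort(config)
  ann <- cohort$annotation
  pooled <- cohort$pooled_genotypes

  # variant-selection bookkeeping (the synthetic panel plays the role of the
  # pre-selected candidate set; classes are reported, not used as a filter)
  candidates <- tryCatch(
    suppressWarnings(select_candidate_variants(cohort$gwas, pooled)),
    error = function(e) NULL)

  eqtl <- list()
  pb_first <- NULL
  for (d in seq_along(cohort$datasets)) {
    ds <- cohort$datasets[[d]]
    pbs <- normalize_and_pseudobulk(ds$cells, min_cells = min_cells)
    adj <- lapply(pbs, adjust_covariates, cov = ds$covariates,
                  n_hidden = n_hidden)
    if (d == 1) pb_first <- adj
    zs <- lapply(adj, zscale)
    recs <- lapply(zs, map_cis, genotypes = ds$genotypes, annotation = ann,
                   dataset = sprintf("D%d", d))
    eqtl[[d]] <- do.call(rbind, recs)
  }
  meta <- meta_analyze(eqtl, min_k = 2)

  n_pairs <- nrow(unique(meta[, c("gene_id", "variant_id")]))
  thr1 <- bonferroni_threshold(alpha, max(n_pairs, 1))$exact
  sig_records <- meta[meta$p_re2 <= thr1, , drop = FALSE]
  sig <- unique(sig_records[, c("gene_id", "cell_type")])

  ld <- ld_r(pooled)
  gwas_pos <- cohort$gwas

  # per-eGene eQTL LD chunks (cross-cell-type min p per variant)
  eqtl_chunks <- NULL
  if (nrow(sig_records)) {
    chunks_per_gene <- lapply(unique(sig_records$gene_id), function(g) {
      mr <- meta[meta$gene_id == g, , drop = FALSE]
      pm <- stats::aggregate(p_re2 ~ variant_id, data = mr, FUN = min)
      st <- data.frame(snp = pm$variant_id, p = pm$p_re2,
                       chr = gwas_pos$chr[match(pm$variant_id, gwas_pos$snp)],
                       bp = gwas_pos$bp[match(pm$variant_id, gwas_pos$snp)],
                       stringsAsFactors = FALSE)
      cl <- clump(st, ld, p1 = thr1, p2 = thr1)
      if (nrow(cl)) cl$gene_id <- g
      cl
    })
    eqtl_chunks <- do.call(rbind, chunks_per_gene)
  }

  gwas_clumps <- clump(cohort$gwas, ld, p1 = 5e-8, p2 = 5e-8)
  gwas_chunks <- if (nrow(gwas_clumps)) clump_spans(gwas_clumps, cohort$gwas)
                 else data.frame(chunk_id = character(), lead = character(),
                                 chr = character(), start = integer(),
                                 end = integer(), n_members = integer())

  gwas_h <- harmonize_alleles(cohort$gwas, cohort$panel)
  coloc <- pair_and_run(meta, sig, gwas_h, gwas_chunks, ann,
                        threshold = pp4_threshold)
  smr <- run_smr(meta, sig, gwas_h, ld)

  ase_pb <- pseudobulk_ase(cohort$ase, min_umis = 20)
  ase_res <- ase_test_all(ase_pb, alpha = ase_alpha)
  conc <- ase_concordance(ase_res, meta)

  dyn_pairs <- if (nrow(sig_records))
    unique(sig_records[, c("gene_id", "variant_id")]) else NULL
  dynamic <- NULL
  if (!is.null(dyn_pairs) && nrow(dyn_pairs)) {
    ds1 <- cohort$datasets[[1]]
    dyn_list <- lapply(pb_first, dynamic_interaction,
                       genotypes = ds1$genotypes, cov = ds1$covariates,
                       pairs = dyn_pairs, alpha = dynamic_alpha)
    dynamic <- do.call(rbind, dyn_list)
    rownames(dynamic) <- NULL
  }

  bulk_meta <- NULL
  if (bulk_n_datasets > 0) {
    bcfg <- config
    bcfg$n_subjects <- bulk_n_subjects
    bulk_recs <- list()
    for (b in seq_len(bulk_n_datasets)) {
      subjects <- sprintf("B%d_S%d", b, seq_len(bulk_n_subjects))
      gt <- simulate_genotypes(bcfg, cohort$panel, subjects)
      cov <- simulate_covariates(bcfg, subjects)
      cells <- simulate_cells(bcfg, gt, cov, cohort$truth, ann,
                              dataset = sprintf("B%d", b))
      cells$cell_meta$cell_type <- "bulk"   # tissue-level mixture
      pb <- normalize_and_pseudobulk(cells, min_cells = min_cells)[["bulk"]]
      pb <- zscale(adjust_covariates(pb, cov, n_hidden = n_hidden))
      bulk_recs[[b]] <- map_cis(pb, gt, ann, dataset = sprintf("B%d", b))
    }
    bulk_meta <- meta_analyze(bulk_recs, min_k = 2)
  }

  tiers <- apply_four_tiers(meta, coloc, smr, alpha = alpha,
                            pp4_threshold = pp4_threshold,
                            heidi_alpha = heidi_alpha,
                            heidi_missing = heidi_missing)
  genes <- annotate_evidence(tiers, ase = ase_res, bulk_meta = bulk_meta,
                             dynamic = dynamic, ase_alpha = ase_alpha,
                             bulk_fdr = bulk_fdr,
                             dynamic_alpha = dynamic_alpha)

  report <- build_report(genes, tiers, meta, coloc, cohort)

  n_chunks <- if (is.null(eqtl_chunks) || !nrow(eqtl_chunks)) 0L
              else length(unique(paste(eqtl_chunks$gene_id,
                                       eqtl_chunks$chunk_id)))
  n_egenes <- length(unique(sig_records$gene_id))
  manifest <- list(
    package_version = as.character(utils::packageVersion("snqtl")),
    seed = config$seed,
    n_subjects = config$n_subjects, n_datasets = config$n_datasets,
    thresholds = list(tier1_bonferroni = thr1,
                      tier3_bonferroni = tiers$thresholds$tier3,
                      pp4 = pp4_threshold, heidi = heidi_alpha,
                      ase = ase_alpha, bulk_fdr = bulk_fdr,
                      dynamic = dynamic_alpha),
    counts = list(
      candidate_classes = as.list(attr(candidates, "class_counts") %||%
                                    list()),
      n_pairs_tested = n_pairs,
      n_meta_records = nrow(meta),
      n_significant_records = nrow(sig_records),
      n_egenes = n_egenes,
      n_independent_eqtls = n_chunks,
      n_additional_eqtls = max(0L, n_chunks - n_egenes),
      n_gwas_chunks = nrow(gwas_chunks),
      n_coloc_pairs = nrow(coloc),
      n_smr_tests = nrow(smr),
      n_ase_tests = nrow(ase_res),
      n_dynamic_tests = if (is.null(dynamic)) 0L else nrow(dynamic),
      n_prioritized = sum(genes$prioritized)))

  out <- list(cohort = cohort, candidates = candidates, eqtl = eqtl,
              meta = meta, eqtl_chunks = eqtl_chunks,
              gwas_chunks = gwas_chunks, coloc = coloc, smr = smr,
              ase = ase_res, concordance = conc, dynamic = dynamic,
              bulk_meta = bulk_meta, tiers = tiers, genes = genes,
              report = report, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# Table-1-style final report: one row per prioritized gene
build_report <- function(genes, tiers, meta, coloc, cohort) {
  pri <- genes[genes$prioritized, , drop = FALSE]
  if (!nrow(pri))
    return(data.frame(locus = integer(), chr = character(),
                      esnp = character(), pos = integer(), a1 = character(),
                      a2 = character(), af = numeric(), gene_id = character(),
                      cell_types = character(), beta = numeric(),
                      se = numeric(), p = numeric(), pp4 = numeric(),
                      ase_support = logical(), bulk_replicated = logical(),
                      dynamic_eqtl = logical()))
  panel <- cohort$panel
  rows <- lapply(seq_len(nrow(pri)), function(i) {
    g <- pri$gene_id[i]
    mr <- meta[meta$gene_id == g, , drop = FALSE]
    best <- mr[which.min(mr$p_re2), ]
    vr <- panel[panel$id == best$variant_id, ]
    cc <- coloc[coloc$gene_id == g, , drop = FALSE]
    data.frame(locus = vr$locus %||% NA_integer_, chr = vr$chrom,
               esnp = vr$id, pos = vr$pos, a1 = vr$a1, a2 = vr$a2,
               af = round(vr$eaf, 2), gene_id = g,
               cell_types = pri$cell_types[i],
               beta = round(best$beta_re, 3), se = round(best$se_re, 3),
               p = best$p_re2,
               pp4 = if (nrow(cc)) round(max(cc$pp4), 2) else NA_real_,
               ase_support = pri$ase_support[i],
               bulk_replicated = pri$bulk_replicated[i],
               dynamic_eqtl = pri$dynamic_eqtl[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) if (!is.null(df) && nrow(df))
    write_table(df, file.path(out_dir, name))
  wt(do.call(rbind, out$eqtl), "eqtl_records.tsv")
  wt(out$meta, "meta_records.tsv")
  wt(out$eqtl_chunks, "eqtl_chunks.tsv")
  wt(out$gwas_chunks, "gwas_chunks.tsv")
  wt(out$coloc, "coloc.tsv")
  wt(out$smr, "smr.tsv")
  wt(out$ase, "ase.tsv")
  wt(out$dynamic, "dynamic.tsv")
  wt(out$bulk_meta, "bulk_meta.tsv")
  wt(out$genes, "risk_genes.tsv")
  wt(out$report, "report.tsv")
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
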