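#' Wakefield log approximate Bayes factor
#'
#' With `z = beta/se`, `V = se^2`, `W = sd_prior^2` and `r = W/(V+W)`:
#' `lABF = 0.5 log(1 - r) + 0.5 r z^2`. Vectorized.
#'
#' @param beta effect estimates.
#' @param se standard errors (> 0).
#' @param sd_prior prior SD of the true effect (`W^0.5`); 0.15 is the
#'   quantitative-trait default, 0.2 the case-control (log-odds) default.
#' @return log ABFs.
#' @export
wakefield_labf <- function(beta, se, sd_prior = 0.15) {
  stopifnot(all(se > 0), sd_prior > 0)
  z <- beta / se
  V <- se^2
  r <- sd_prior^2 / (V + sd_prior^2)
  0.5 * log(1 - r) + 0.5 * r * z^2
}

#' Log ABFs reconstructed from p, MAF and N
#'
#' When betas/SEs are unavailable for a trait the sampling variance is
#' approximated by `V = 1/(2 N maf (1 - maf))` (unit-variance quantitative
#' phenotype) and `|z|` recovered from the p-value.
#'
#' @param p two-sided p-values.
#' @param maf minor-allele frequencies.
#' @param n sample sizes.
#' @param sd_prior prior SD as in [wakefield_labf()].
#' @return log ABFs.
#' @export
labf_from_pn <- function(p, maf, n, sd_prior = 0.15) {
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  V <- 1 / (2 * n * maf * (1 - maf))
  wakefield_labf(z * sqrt(V), sqrt(V), sd_prior)
}

#' Five-hypothesis colocalization posteriors
#'
#' Single-causal-variant model. With per-SNP log ABFs for the two traits,
#' the hypothesis evidences are `L1 = logsum(labf1)`, `L2 = logsum(labf2)`,
#' `L12 = logsum(labf1 + labf2)` and the posteriors are proportional to
#' `{1, p1 e^L1, p2 e^L2, p1 p2 (e^(L1+L2) - e^L12), p12 e^L12}`.
#' Negative H3 mass (possible with a single SNP) is clipped at zero.
#'
#' @param labf1,labf2 per-SNP log ABFs on the same SNP ordering.
#' @param p1,p2 prior probability a SNP is associated with trait 1 / 2
#'   (default 1e-4 each).
#' @param p12 prior probability a SNP is associated with both (default 1e-5).
#' @return named numeric `pp0`..`pp4` (sums to 1) with attribute `n_snps`.
#' @export
coloc_posteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (!length(labf1)) stop("empty SNP set")
  stopifnot(length(labf1) == length(labf2))
  L1 <- logsumexp(labf1)
  L2 <- logsumexp(labf2)
  L12 <- logsumexp(labf1 + labf2)
  lh <- c(0,
          log(p1) + L1,
          log(p2) + L2,
          log(p1) + log(p2) + logdiffexp(L1 + L2, L12),
          log(p12) + L12)
  if (length(labf1) == 1 && lh[4] > -Inf)
    lh[4] <- -Inf  # one SNP cannot support distinct causal variants
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  names(pp) <- paste0("pp", 0:4)
  attr(pp, "n_snps") <- length(labf1)
  pp
}

#' Pair significant eQTL signals with GWAS chunks and colocalize
#'
#' For each significant gene x cell type and each GWAS LD chunk overlapping
#' the gene's cis window, intersects the SNP sets, computes expression-side
#' log ABFs from the meta RE effect/SE (prior SD `sd_prior_eqtl`) and
#' GWAS-side log ABFs from the harmonized summary statistics (prior SD
#' `sd_prior_gwas`, log-odds scale), and runs [coloc_posteriors()].
#'
#' @param meta_records meta records with `chunk-testable` RE stats
#'   (`beta_re`, `se_re`) for all cis variants of each gene/cell type.
#' @param sig data.frame of significant gene x cell-type combinations
#'   (`gene_id`, `cell_type`).
#' @param gwas harmonized GWAS [sumstats()].
#' @param gwas_chunks spans from [clump_spans()] of the GWAS clumps.
#' @param annotation gene annotation.
#' @param window_bp cis window (default 1 Mb).
#' @param span_pad_bp padding added around each chunk span when collecting
#'   SNPs (default 500 kb, the clumping distance window). A clump's span
#'   covers only its members — genome-wide-significant variants — and can
#'   degenerate to a single position; the padded region restores the LD
#'   neighbourhood that a meaningful linkage-vs-sharing comparison needs.
#' @param sd_prior_eqtl,sd_prior_gwas Wakefield prior SDs (0.15 / 0.2).
#' @param p1,p2,p12 hypothesis priors.
#' @param threshold PP4 pass threshold (default 0.8).
#' @return data.frame: `gene_id`, `cell_type`, `chunk_id`, `n_snps`,
#'   `pp0`..`pp4`, `pass`.
#' @export
pair_and_run <- function(meta_records, sig, gwas, gwas_chunks, annotation,
                         window_bp = 1e6, span_pad_bp = 5e5,
                         sd_prior_eqtl = 0.15, sd_prior_gwas = 0.2,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, threshold = 0.8) {
  out <- list()
  for (i in seq_len(nrow(sig))) {
    g <- sig$gene_id[i]; ct <- sig$cell_type[i]
    ann <- annotation[annotation$gene_id == g, , drop = FALSE]
    if (!nrow(ann)) next
    lo <- ann$start[1] - window_bp; hi <- ann$end[1] + window_bp
    mr <- meta_records[meta_records$gene_id == g &
                         meta_records$cell_type == ct, , drop = FALSE]
    if (!nrow(mr)) next
    ch <- gwas_chunks[gwas_chunks$chr == ann$chrom[1] &
                        gwas_chunks$end >= lo & gwas_chunks$start <= hi, ,
                      drop = FALSE]
    for (j in seq_len(nrow(ch))) {
      gsub <- gwas[gwas$chr == ch$chr[j] &
                     gwas$bp >= ch$start[j] - span_pad_bp &
                     gwas$bp <= ch$end[j] + span_pad_bp, , drop = FALSE]
      snps <- intersect(mr$variant_id, gsub$snp)
      if (!length(snps)) next
      e <- mr[match(snps, mr$variant_id), , drop = FALSE]
      w <- gsub[match(snps, gsub$snp), , drop = FALSE]
      pp <- coloc_posteriors(wakefield_labf(e$beta_re, e$se_re, sd_prior_eqtl),
                             wakefield_labf(w$beta, w$se, sd_prior_gwas),
                             p1 = p1, p2 = p2, p12 = p12)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, cell_type = ct, chunk_id = ch$chunk_id[j],
        n_snps = length(snps), pp0 = pp[1], pp1 = pp[2], pp2 = pp[3],
        pp3 = pp[4], pp4 = pp[5], pass = unname(pp[5]) >= threshold,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(gene_id = character(), cell_type = character(),
                      chunk_id = character(), n_snps = integer(),
                      pp0 = numeric(), pp1 = numeric(), pp2 = numeric(),
                      pp3 = numeric(), pp4 = numeric(), pass = logical()))
  rownames(res) <- NULL
  res
}
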