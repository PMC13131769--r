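#' Single-SNP summary-based Mendelian randomization
#'
#' Uses the top eSNP as an instrument: `b_xy = b_gwas / b_eqtl` (trait units
#' per SD of expression), with the SMR chi-square statistic
#' `T = z_g^2 z_e^2 / (z_g^2 + z_e^2)` and `p` from the upper chisq(1)
#' tail. Weak instruments (|z_e| < `min_instrument_z`) are rejected.
#'
#' @param b_gwas,se_gwas GWAS effect and SE at the instrument.
#' @param b_eqtl,se_eqtl eQTL effect and SE at the instrument.
#' @param min_instrument_z minimum |z| of the eQTL instrument (default 3).
#' @return list `b_xy`, `se_xy`, `T`, `p`.
#' @export
smr_single <- function(b_gwas, se_gwas, b_eqtl, se_eqtl,
                       min_instrument_z = 3) {
  stopifnot(se_gwas > 0, se_eqtl > 0)
  z_e <- b_eqtl / se_eqtl
  if (abs(z_e) < min_instrument_z)
    stop("instrument too weak: |z_eqtl| = ", round(abs(z_e), 2), " < ",
         min_instrument_z)
  z_g <- b_gwas / se_gwas
  b_xy <- b_gwas / b_eqtl
  if (z_g == 0)
    return(list(b_xy = b_xy, se_xy = Inf, T = 0, p = 1))
  T <- z_g^2 * z_e^2 / (z_g^2 + z_e^2)
  list(b_xy = b_xy, se_xy = abs(b_xy) / sqrt(T), T = T,
       p = stats::pchisq(T, 1, lower.tail = FALSE))
}

# select HEIDI candidate SNPs around a top eSNP: eQTL p below the gate, r2
# to the top inside the window, pruned so no retained pair exceeds the upper
# r2 bound, truncated to the strongest eQTL |z|
heidi_select <- function(top, eqtl, ld, peqtl = 1.57e-3,
                         r2_window = c(0.05, 0.9), max_snps = 20) {
  cand <- eqtl$variant_id[eqtl$p < peqtl & eqtl$variant_id != top]
  cand <- cand[cand %in% rownames(ld)]
  if (!length(cand)) return(character(0))
  r2top <- ld[top, cand]^2
  cand <- cand[r2top >= r2_window[1] & r2top <= r2_window[2]]
  if (!length(cand)) return(character(0))
  z <- abs(eqtl$beta / eqtl$se)[match(cand, eqtl$variant_id)]
  cand <- cand[order(-z)]
  keep <- character(0)
  for (v in cand) {
    if (!length(keep) || all(ld[v, keep]^2 <= r2_window[2])) keep <- c(keep, v)
    if (length(keep) >= max_snps) break
  }
  keep
}

#' HEIDI heterogeneity-in-dependent-instruments test
#'
#' Distinguishes a single shared causal variant (non-significant) from
#' linkage between distinct causal variants (significant) by testing
#' whether `b_xy` estimated from LD neighbours of the top eSNP differs from
#' `b_xy` at the top eSNP. Differences `d_i = b_xy(i) - b_xy(top)` get a
#' delta-method covariance in which summary statistics at SNP pairs
#' correlate with the LD `r` (same-cohort approximation); the statistic
#' `S = sum z_d^2` is referred to a Satterthwaite-matched scaled
#' chi-square using the eigenstructure of the `z_d` correlation matrix.
#' Downstream, a gene passes when `p_heidi >= 0.01`.
#'
#' @param top top eSNP id.
#' @param eqtl allele-harmonized cis eQTL stats (`variant_id`, `beta`,
#'   `se`, `p`).
#' @param gwas allele-harmonized GWAS stats (`snp`, `beta`, `se`).
#' @param ld signed LD correlation matrix covering all candidates.
#' @param peqtl candidate eQTL p gate (default 1.57e-3).
#' @param r2_window candidate r2-to-top window (default `[0.05, 0.9]`).
#' @param max_snps,min_snps candidate-count bounds (default 20 / 3).
#' @return list `p` (`NA` when fewer than `min_snps` candidates remain),
#'   `n_used`, `snps`.
#' @export
heidi <- function(top, eqtl, gwas, ld, peqtl = 1.57e-3,
                  r2_window = c(0.05, 0.9), max_snps = 20, min_snps = 3) {
  sel <- heidi_select(top, eqtl, ld, peqtl, r2_window, max_snps)
  if (length(sel) < min_snps)
    return(list(p = NA_real_, n_used = 0L, snps = character(0)))
  snps <- c(top, sel)
  be <- eqtl$beta[match(snps, eqtl$variant_id)]
  se_e <- eqtl$se[match(snps, eqtl$variant_id)]
  bg <- gwas$beta[match(snps, gwas$snp)]
  se_g <- gwas$se[match(snps, gwas$snp)]
  if (anyNA(c(be, se_e, bg, se_g)))
    return(list(p = NA_real_, n_used = 0L, snps = character(0)))
  R <- ld[snps, snps]
  m <- length(sel)
  bxy <- bg / be
  # cov(b_xy_i, b_xy_j) by the delta method with cor(b_g_i, b_g_j) =
  # cor(b_e_i, b_e_j) = r_ij and gwas/eqtl stats independent
  cov_xy <- matrix(0, m + 1, m + 1)
  for (i in seq_len(m + 1)) for (j in seq_len(m + 1)) {
    cov_xy[i, j] <- R[i, j] * se_g[i] * se_g[j] / (be[i] * be[j]) +
      bg[i] * bg[j] / (be[i]^2 * be[j]^2) * R[i, j] * se_e[i] * se_e[j]
  }
  # d_i = b_xy(i) - b_xy(top); top is index 1
  A <- cbind(-1, diag(m))
  cov_d <- A %*% cov_xy %*% t(A)
  vd <- diag(cov_d)
  if (any(vd <= 0)) return(list(p = NA_real_, n_used = 0L, snps = character(0)))
  d <- bxy[-1] - bxy[1]
  z_d <- d / sqrt(vd)
  C <- cov_d / sqrt(vd %o% vd)
  ev <- tryCatch(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev)) {
    C <- C + diag(1e-6, m)
    message("heidi: ridge 1e-6 added to a singular correlation matrix")
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  }
  S <- sum(z_d^2)
  ES <- m
  VS <- 2 * sum(ev^2)
  scale <- VS / (2 * ES)
  df <- 2 * ES^2 / VS
  list(p = stats::pchisq(S / scale, df, lower.tail = FALSE),
       n_used = m, snps = sel)
}

#' Multi-SNP SMR test
#'
#' Sums the per-SNP SMR statistics over the HEIDI-selected SNP set plus the
#' top eSNP and refers the sum to a Satterthwaite-matched scaled chi-square
#' whose moments come from the eigenvalues of the SNPs' signed LD
#' correlation matrix. Reduces to the single-SNP test for one SNP.
#'
#' @param snps SNP ids (top eSNP plus selected set).
#' @param eqtl,gwas allele-harmonized stats as in [heidi()].
#' @param ld signed LD correlation matrix.
#' @return list `p`, `S`, `n_snps`.
#' @export
smr_multi <- function(snps, eqtl, gwas, ld) {
  be <- eqtl$beta[match(snps, eqtl$variant_id)]
  se_e <- eqtl$se[match(snps, eqtl$variant_id)]
  bg <- gwas$beta[match(snps, gwas$snp)]
  se_g <- gwas$se[match(snps, gwas$snp)]
  z_e <- be / se_e; z_g <- bg / se_g
  T <- z_g^2 * z_e^2 / (z_g^2 + z_e^2)
  S <- sum(T)
  if (length(snps) == 1)
    return(list(p = stats::pchisq(S, 1, lower.tail = FALSE), S = S,
                n_snps = 1L))
  R <- ld[snps, snps]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ES <- length(snps)
  VS <- 2 * sum(ev^2)
  scale <- VS / (2 * ES)
  df <- 2 * ES^2 / VS
  list(p = stats::pchisq(S / scale, df, lower.tail = FALSE), S = S,
       n_snps = length(snps))
}

#' Run SMR + HEIDI for significant genes per cell type
#'
#' For each gene x cell type: the top eSNP is the cis variant with the
#' smallest meta p (RE2) whose eQTL instrument satisfies
#' |z| >= `min_instrument_z`; single-SNP SMR uses the RE effect/SE against
#' the GWAS, then HEIDI and the multi-SNP test run over the selected
#' neighbourhood.
#'
#' @param meta_records meta records for all cis variants (RE beta/se, RE2
#'   p) of the genes to test.
#' @param sig data.frame of gene x cell-type combinations to test.
#' @param gwas harmonized GWAS [sumstats()].
#' @param ld signed LD correlation matrix over the cis variants.
#' @param min_instrument_z instrument gate (default 3).
#' @param peqtl_heidi,heidi_r2_window,heidi_max_snps,heidi_min_snps HEIDI
#'   selection parameters.
#' @return data.frame: `gene_id`, `cell_type`, `top_esnp`, `b_xy`, `se_xy`,
#'   `p_smr`, `p_smr_multi`, `p_heidi`, `n_heidi_snps`.
#' @export
run_smr <- function(meta_records, sig, gwas, ld, min_instrument_z = 3,
                    peqtl_heidi = 1.57e-3, heidi_r2_window = c(0.05, 0.9),
                    heidi_max_snps = 20, heidi_min_snps = 3) {
  out <- list()
  for (i in seq_len(nrow(sig))) {
    g <- sig$gene_id[i]; ct <- sig$cell_type[i]
    mr <- meta_records[meta_records$gene_id == g &
                         meta_records$cell_type == ct, , drop = FALSE]
    mr <- mr[mr$variant_id %in% gwas$snp & mr$variant_id %in% rownames(ld), ,
             drop = FALSE]
    if (!nrow(mr)) next
    z_e <- abs(mr$beta_re / mr$se_re)
    mr_ok <- mr[z_e >= min_instrument_z, , drop = FALSE]
    if (!nrow(mr_ok)) next
    top <- mr_ok$variant_id[which.min(mr_ok$p_re2)]
    tr <- mr_ok[mr_ok$variant_id == top, ]
    gw <- gwas[match(top, gwas$snp), ]
    sm <- smr_single(gw$beta, gw$se, tr$beta_re, tr$se_re,
                     min_instrument_z = min_instrument_z)
    eq <- data.frame(variant_id = mr$variant_id, beta = mr$beta_re,
                     se = mr$se_re, p = mr$p_re2, stringsAsFactors = FALSE)
    hd <- heidi(top, eq, gwas, ld, peqtl = peqtl_heidi,
                r2_window = heidi_r2_window, max_snps = heidi_max_snps,
                min_snps = heidi_min_snps)
    snps_multi <- c(top, hd$snps)
    pm <- smr_multi(snps_multi, eq, gwas, ld)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g, cell_type = ct, top_esnp = top, b_xy = sm$b_xy,
      se_xy = sm$se_xy, p_smr = sm$p, p_smr_multi = pm$p,
      p_heidi = hd$p, n_heidi_snps = hd$n_used, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(gene_id = character(), cell_type = character(),
                      top_esnp = character(), b_xy = numeric(),
                      se_xy = numeric(), p_smr = numeric(),
                      p_smr_multi = numeric(), p_heidi = numeric(),
                      n_heidi_snps = integer()))
  rownames(res) <- NULL
  res
}
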