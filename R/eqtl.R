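#' Marginal OLS of one phenotype on many dosage columns
#'
#' Closed-form simple regression of `y` on each column of `X` with pairwise
#' exclusion of missing dosages, returning slope, standard error, t and the
#' two-sided t-tail p at `n - 2` df. Workhorse behind [map_cis()].
#'
#' @param y numeric phenotype (no `NA`; filter first).
#' @param X dosage matrix (subjects x variants, `NA` allowed).
#' @return data.frame with `beta`, `se`, `t`, `p`, `n` per column of `X`.
#' @export
marginal_ols <- function(y, X) {
  M <- !is.na(X)
  Xz <- X; Xz[!M] <- 0
  n <- colSums(M)
  Sx <- colSums(Xz)
  Sxx <- colSums(Xz^2)
  Sy <- drop(crossprod(M, y))
  Syy <- drop(crossprod(M, y^2))
  Sxy <- drop(crossprod(Xz, y))
  vx <- Sxx - Sx^2 / n
  vy <- Syy - Sy^2 / n
  cxy <- Sxy - Sx * Sy / n
  beta <- cxy / vx
  rss <- vy - beta * cxy
  df <- n - 2
  sigma2 <- rss / df
  sigma2[sigma2 < 0] <- 0
  se <- sqrt(sigma2 / vx)
  t <- beta / se
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(beta = beta, se = se, t = t, p = p, n = n,
             row.names = NULL)
}

#' Select candidate risk variants in three classes
#'
#' Class 1: GWAS p <= `p1` (genome-wide significant). Class 2: GWAS
#' p <= `p2` within `window_bp` of a locus lead. Class 3: LD proxies with
#' r2 >= `r2_proxy` to any class-1/2 variant. Variants with reference-panel
#' MAF < `maf_min` are removed first.
#'
#' @param gwas a [sumstats()] table with `chr`/`bp`.
#' @param genotypes LD-reference [genotype_matrix()].
#' @param leads data.frame of locus leads with `chrom` and `pos` (defaults
#'   to the class-1 variants themselves).
#' @param p1,p2 class-1 and class-2 p-value gates (defaults 5e-8, 1e-6).
#' @param window_bp distance window around leads for class 2 (default 2 Mb).
#' @param r2_proxy proxy r2 gate (default 0.4).
#' @param maf_min reference MAF filter (default 0.05).
#' @return data.frame `variant_id`, `class` (1/2/3) with attribute
#'   `class_counts` (named counts plus total).
#' @export
select_candidate_variants <- function(gwas, genotypes, leads = NULL,
                                      p1 = 5e-8, p2 = 1e-6,
                                      window_bp = 2e6, r2_proxy = 0.4,
                                      maf_min = 0.05) {
  stopifnot(all(c("chr", "bp") %in% names(gwas)))
  eaf <- genotypes$variants$eaf[match(gwas$snp, genotypes$variants$id)]
  maf <- pmin(eaf, 1 - eaf)
  g <- gwas[!is.na(maf) & maf >= maf_min, , drop = FALSE]

  class1 <- g$snp[g$p <= p1]
  if (is.null(leads)) {
    leads <- g[g$snp %in% class1, c("chr", "bp")]
    names(leads) <- c("chrom", "pos")
  }
  near_lead <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(leads))) {
    near_lead <- near_lead |
      (g$chr == leads$chrom[i] & abs(g$bp - leads$pos[i]) <= window_bp)
  }
  class2 <- setdiff(g$snp[g$p <= p2 & near_lead], class1)

  seed_ids <- c(class1, class2)
  class3 <- character(0)
  if (length(seed_ids)) {
    rest <- setdiff(g$snp, seed_ids)
    rest <- rest[rest %in% genotypes$variants$id]
    if (length(rest)) {
      r <- stats::cor(genotypes$dosage[, rest, drop = FALSE],
                      genotypes$dosage[, seed_ids, drop = FALSE],
                      use = "pairwise.complete.obs")
      class3 <- rest[apply(r^2, 1, max, na.rm = TRUE) >= r2_proxy]
    }
  }
  out <- data.frame(
    variant_id = c(class1, class2, class3),
    class = rep(1:3, c(length(class1), length(class2), length(class3))),
    stringsAsFactors = FALSE)
  counts <- c(class1 = length(class1), class2 = length(class2),
              class3 = length(class3), total = nrow(out))
  attr(out, "class_counts") <- counts
  if (nrow(out) == 0) warning("no candidate variants selected")
  out
}

#' Map cis-eQTLs for one cell type
#'
#' For each gene and each candidate variant on the same chromosome with
#' position in `[start - window_bp, end + window_bp]` (inclusive), fits an
#' ordinary least-squares regression of z-scaled pseudobulk expression on
#' dosage (covariates were already residualized out) and reports the
#' two-sided t test. Pairs with fewer than `min_n` complete subjects, or
#' with zero dosage variance among them, are skipped with a logged count.
#'
#' @param pb a [pseudobulk()] in state `zscaled`.
#' @param genotypes a [genotype_matrix()].
#' @param annotation gene annotation data.frame.
#' @param candidates optional character vector restricting the variants
#'   tested (e.g. from [select_candidate_variants()]).
#' @param window_bp cis window (default 1 Mb).
#' @param min_n minimum complete subjects per pair (default 20).
#' @param dataset label stored in the output.
#' @return data.frame of eQTL records: `gene_id`, `variant_id`, `cell_type`,
#'   `dataset`, `beta` (SD per `a1` allele), `se`, `t`, `p`, `n`.
#' @export
map_cis <- function(pb, genotypes, annotation, candidates = NULL,
                    window_bp = 1e6, min_n = 20, dataset = "D1") {
  stopifnot(pb$state == "zscaled")
  subj <- intersect(rownames(pb$values), genotypes$subjects)
  vt <- genotypes$variants
  if (!is.null(candidates)) vt <- vt[vt$id %in% candidates, , drop = FALSE]
  res <- vector("list", nrow(annotation))
  n_skipped <- 0L
  for (gi in seq_len(nrow(annotation))) {
    gene <- annotation$gene_id[gi]
    if (!gene %in% colnames(pb$values)) next
    cis <- vt$id[vt$chrom == annotation$chrom[gi] &
                   vt$pos >= annotation$start[gi] - window_bp &
                   vt$pos <= annotation$end[gi] + window_bp]
    if (!length(cis)) next
    y <- pb$values[subj, gene]
    ok <- !is.na(y)
    if (sum(ok) < min_n) next
    X <- genotypes$dosage[subj[ok], cis, drop = FALSE]
    fit <- marginal_ols(y[ok], X)
    fit$gene_id <- gene
    fit$variant_id <- cis
    keep <- fit$n >= min_n & is.finite(fit$beta) & is.finite(fit$se) &
      fit$se > 0
    n_skipped <- n_skipped + sum(!keep)
    res[[gi]] <- fit[keep, , drop = FALSE]
  }
  if (n_skipped > 0)
    message("map_cis: skipped ", n_skipped,
            " pair(s) with low n or zero dosage variance")
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(gene_id = character(), variant_id = character(),
                      cell_type = character(), dataset = character(),
                      beta = numeric(), se = numeric(), t = numeric(),
                      p = numeric(), n = integer()))
  out$cell_type <- pb$cell_type
  out$dataset <- dataset
  rownames(out) <- NULL
  out[, c("gene_id", "variant_id", "cell_type", "dataset",
          "beta", "se", "t", "p", "n")]
}

#' Genotype-by-pathology (dynamic) eQTL interaction test
#'
#' Per eQTL pair, fits `expression ~ dosage + score + dosage:score` on
#' residualized (or z-scaled) pseudobulk expression and reports the
#' interaction coefficient's two-sided t test. Records with interaction
#' p <= `alpha` are flagged dynamic. Variables enter raw by default;
#' `center = TRUE` centers dosage and score first.
#'
#' @param pb a [pseudobulk()] (state `residualized` or `zscaled`).
#' @param genotypes a [genotype_matrix()].
#' @param cov covariates with `subject_id` and `pathology_score`.
#' @param pairs data.frame with `gene_id` and `variant_id` rows to test.
#' @param center center dosage and score before fitting (default `FALSE`).
#' @param alpha dynamic flag threshold (default 0.01).
#' @param min_n minimum complete subjects (default 20).
#' @return data.frame with `gene_id`, `variant_id`, `cell_type`,
#'   `beta_interaction`, `se_interaction`, `p_interaction`, `n`, `dynamic`.
#' @export
dynamic_interaction <- function(pb, genotypes, cov, pairs, center = FALSE,
                                alpha = 0.01, min_n = 20) {
  stopifnot(pb$state %in% c("residualized", "zscaled"))
  score_all <- cov$pathology_score[match(genotypes$subjects, cov$subject_id)]
  if (length(unique(stats::na.omit(score_all))) < 2) {
    warning("pathology score is constant; no dynamic eQTLs computable")
    return(data.frame(gene_id = character(), variant_id = character(),
                      cell_type = character(), beta_interaction = numeric(),
                      se_interaction = numeric(), p_interaction = numeric(),
                      n = integer(), dynamic = logical()))
  }
  subj <- intersect(rownames(pb$values), genotypes$subjects)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    gene <- pairs$gene_id[i]; var <- pairs$variant_id[i]
    if (!gene %in% colnames(pb$values) ||
        !var %in% genotypes$variants$id) next
    y <- pb$values[subj, gene]
    x <- genotypes$dosage[subj, var]
    s <- cov$pathology_score[match(subj, cov$subject_id)]
    ok <- !is.na(y) & !is.na(x) & !is.na(s)
    if (sum(ok) < min_n) next
    y <- y[ok]; x <- x[ok]; s <- s[ok]
    if (center) { x <- x - mean(x); s <- s - mean(s) }
    Xm <- cbind(1, x, s, x * s)
    qf <- qr(Xm)
    if (qf$rank < 4) next
    cf <- qr.coef(qf, y)
    rs <- y - Xm %*% cf
    df <- length(y) - 4
    sigma2 <- sum(rs^2) / df
    XtXinv <- chol2inv(qr.R(qf))
    se <- sqrt(sigma2 * XtXinv[4, 4])
    tval <- cf[4] / se
    out[[i]] <- data.frame(gene_id = gene, variant_id = var,
                           cell_type = pb$cell_type,
                           beta_interaction = unname(cf[4]),
                           se_interaction = se,
                           p_interaction = 2 * stats::pt(-abs(tval), df),
                           n = length(y), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(gene_id = character(), variant_id = character(),
                      cell_type = character(), beta_interaction = numeric(),
                      se_interaction = numeric(), p_interaction = numeric(),
                      n = integer(), dynamic = logical()))
  res$dynamic <- res$p_interaction <= alpha
  rownames(res) <- NULL
  res
}
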