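#' Pairwise LD correlation of dosage columns
#'
#' Signed Pearson correlation over complete pairs; square it for r2.
#'
#' @param genotypes a [genotype_matrix()].
#' @param ids optional variant ids to restrict to.
#' @return symmetric correlation matrix with variant-id dimnames.
#' @export
ld_r <- function(genotypes, ids = NULL) {
  X <- genotypes$dosage
  if (!is.null(ids)) {
    j <- match(ids, genotypes$variants$id)
    if (anyNA(j)) stop("unknown variant id(s): ",
                       paste(ids[is.na(j)], collapse = ", "))
    X <- X[, j, drop = FALSE]
  }
  if (ncol(X) < 2) stop("ld_r needs at least 2 variants")
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  if (any(v == 0, na.rm = TRUE))
    stop("variant(s) with zero dosage variance: ",
         paste(colnames(X)[which(v == 0)], collapse = ", "))
  r <- stats::cor(X, use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the unassigned variant with the smallest p <= `p1` as a
#' new lead (ties broken by position, then id) and assigns to it every
#' unassigned variant with p <= `p2`, within `kb` kilobases of the lead on
#' the same chromosome, and r2 >= `r2_thresh` with the lead. Surviving
#' leads are mutually unclumpable. Mirrors the PLINK
#' `--clump-p1/p2/r2/kb` semantics with deterministic tie-breaking;
#' distance is measured lead-to-member.
#'
#' @param stats a [sumstats()]-like data.frame with `snp`, `p`, `chr`, `bp`.
#' @param ld signed correlation matrix from [ld_r()] covering the variants.
#' @param p1 lead p-value gate.
#' @param p2 member p-value gate.
#' @param r2_thresh clumping r2 threshold (default 0.1).
#' @param kb distance window in kilobases (default 500).
#' @return data.frame with `chunk_id`, `lead`, `member`, `p`,
#'   `r2_with_lead`, `distance_bp` (one row per member incl. the lead);
#'   empty when no variant passes `p1`.
#' @export
clump <- function(stats, ld, p1, p2, r2_thresh = 0.1, kb = 500) {
  stopifnot(all(c("snp", "p", "chr", "bp") %in% names(stats)))
  s <- stats[stats$snp %in% rownames(ld), , drop = FALSE]
  ord <- order(s$p, s$bp, s$snp)
  s <- s[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(s))
  res <- list()
  chunk <- 0L
  repeat {
    i <- which(!assigned & s$p <= p1)[1]
    if (is.na(i)) break
    chunk <- chunk + 1L
    lead <- s$snp[i]
    r2 <- ld[lead, s$snp]^2
    memb <- !assigned & s$p <= p2 & s$chr == s$chr[i] &
      abs(s$bp - s$bp[i]) <= kb * 1000 & r2 >= r2_thresh
    memb[i] <- TRUE
    assigned[memb] <- TRUE
    res[[chunk]] <- data.frame(
      chunk_id = sprintf("chunk_%03d", chunk), lead = lead,
      member = s$snp[memb], p = s$p[memb],
      r2_with_lead = unname(r2[memb]),
      distance_bp = abs(s$bp[memb] - s$bp[i]),
      stringsAsFactors = FALSE)
  }
  if (!chunk)
    return(data.frame(chunk_id = character(), lead = character(),
                      member = character(), p = numeric(),
                      r2_with_lead = numeric(), distance_bp = integer()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Span (bp range) of each clump
#' @param clumps output of [clump()].
#' @param stats the summary statistics the clumps came from (for positions).
#' @return data.frame `chunk_id`, `lead`, `chr`, `start`, `end`, `n_members`.
#' @export
clump_spans <- function(clumps, stats) {
  bp <- stats$bp[match(clumps$member, stats$snp)]
  chr <- stats$chr[match(clumps$lead, stats$snp)]
  agg <- split(seq_len(nrow(clumps)), clumps$chunk_id)
  rows <- lapply(names(agg), function(cid) {
    ii <- agg[[cid]]
    data.frame(chunk_id = cid, lead = clumps$lead[ii[1]], chr = chr[ii[1]],
               start = min(bp[ii]), end = max(bp[ii]),
               n_members = length(ii), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign meta records to LD chunks and flag per-cell-type detection
#'
#' Each record is mapped to the chunk its eSNP belongs to; records from
#' different cell types sharing a chunk receive the same eQTL identity.
#' Per chunk and cell type, `detected` is true when any member variant
#' passes `threshold` on the RE2 p in that cell type.
#'
#' @param records meta records (from [meta_analyze()]).
#' @param clumps output of [clump()].
#' @param threshold significance threshold applied to `p_re2`.
#' @return list with `records` (input plus `chunk_id`, `NA` for variants in
#'   no chunk) and `detection` (data.frame `chunk_id`, `gene_id`,
#'   `cell_type`, `detected`).
#' @export
assign_to_chunks <- function(records, clumps, threshold) {
  records$chunk_id <- clumps$chunk_id[match(records$variant_id, clumps$member)]
  inb <- records[!is.na(records$chunk_id), , drop = FALSE]
  key <- unique(inb[, c("chunk_id", "gene_id", "cell_type")])
  key$detected <- mapply(function(ch, g, ct) {
    any(inb$p_re2[inb$chunk_id == ch & inb$gene_id == g &
                    inb$cell_type == ct] <= threshold)
  }, key$chunk_id, key$gene_id, key$cell_type)
  rownames(key) <- NULL
  list(records = records, detection = key)
}

#' Storey pi1 statistic (fixed lambda)
#'
#' `pi0 = min(1, #\{p > lambda\} / (m (1 - lambda)))`; `pi1 = 1 - pi0`.
#' Used to estimate the shared fraction of eQTL signals across cell types.
#'
#' @param pvalues p-values in (0, 1].
#' @param lambda tuning point (default 0.5).
#' @return estimated pi1 in `[0, 1]`.
#' @export
pi1 <- function(pvalues, lambda = 0.5) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  m <- length(pvalues)
  pi0 <- min(1, sum(pvalues > lambda) / (m * (1 - lambda)))
  1 - pi0
}
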