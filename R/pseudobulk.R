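#' Normalize single-cell counts and pseudobulk per cell type
#'
#' Per cell, each gene's UMI count is divided by the cell's total UMI count
#' and multiplied by 10,000 (counts per 10k). Per cell type, a subject's
#' pseudobulk value is the mean of that subject's cells' normalized values.
#' Subjects contributing fewer than `min_cells` cells of a type are set
#' missing (all-`NA` row) for that type. Cells with zero total UMIs are
#' excluded with a logged count.
#'
#' @param counts a [cell_counts()].
#' @param min_cells per-subject cell floor per type (default 10).
#' @return Named list of [pseudobulk()] objects (state `normalized_mean`),
#'   one per cell type, all sharing the full subject set as rows.
#' @export
normalize_and_pseudobulk <- function(counts, min_cells = 10) {
  tot <- Matrix::rowSums(counts$counts)
  zero <- tot == 0
  if (any(zero))
    message("normalize_and_pseudobulk: excluded ", sum(zero),
            " cell(s) with zero total UMIs")
  keep <- which(!zero)
  norm <- counts$counts[keep, , drop = FALSE] / tot[keep] * 1e4
  meta <- counts$cell_meta[keep, , drop = FALSE]
  subjects <- sort(unique(counts$cell_meta$subject_id))
  out <- list()
  for (ct in sort(unique(meta$cell_type))) {
    sel <- meta$cell_type == ct
    grp <- meta$subject_id[sel]
    sums <- rowsum(as.matrix(norm[sel, , drop = FALSE]), grp)
    ncell <- as.vector(table(grp)[rownames(sums)])
    vals <- sums / ncell
    m <- matrix(NA_real_, length(subjects), ncol(vals),
                dimnames = list(subjects, counts$gene_ids))
    ok <- ncell >= min_cells
    m[rownames(sums)[ok], ] <- vals[ok, , drop = FALSE]
    out[[ct]] <- pseudobulk(m, ct, state = "normalized_mean")
  }
  out
}

# ComBat-style parametric empirical-Bayes shrinkage of per-batch location and
# scale, applied gene-wise after standardization; falls back to plain
# centering/rescaling when a batch has < 2 subjects
eb_batch_adjust <- function(x, batch) {
  bt <- unique(batch)
  gm <- colMeans(x)
  gv <- apply(x, 2, stats::var)
  gv[gv == 0] <- 1
  z <- sweep(sweep(x, 2, gm, "-"), 2, sqrt(gv), "/")
  for (b in bt) {
    i <- which(batch == b)
    if (length(i) < 2) next
    g_hat <- colMeans(z[i, , drop = FALSE])            # batch locations
    d_hat <- apply(z[i, , drop = FALSE], 2, stats::var) # batch scales
    # normal prior on location, inverse-gamma on scale (method of moments)
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    if (!is.finite(t2) || t2 <= 0) t2 <- 1e-8
    m_d <- mean(d_hat); v_d <- stats::var(d_hat)
    if (!is.finite(v_d) || v_d <= 0) v_d <- 1e-8
    a_pr <- (2 * v_d + m_d^2) / v_d
    b_pr <- (m_d * v_d + m_d^3) / v_d
    n_b <- length(i)
    g_star <- (n_b * t2 * g_hat + d_hat * g_bar) / (n_b * t2 + d_hat)
    ss <- colSums(sweep(z[i, , drop = FALSE], 2, g_star, "-")^2)
    d_star <- (b_pr + ss / 2) / (n_b / 2 + a_pr - 1)
    d_star[d_star <= 0 | !is.finite(d_star)] <- d_hat[d_star <= 0 | !is.finite(d_star)]
    z[i, ] <- sweep(sweep(z[i, , drop = FALSE], 2, g_star, "-"), 2,
                    sqrt(d_star), "/")
  }
  sweep(sweep(z, 2, sqrt(gv), "*"), 2, gm, "+")
}

# per gene, per batch: center and rescale to the pooled mean/variance
meanvar_batch_adjust <- function(x, batch) {
  gm <- colMeans(x)
  gsd <- apply(x, 2, stats::sd)
  for (b in unique(batch)) {
    i <- which(batch == b)
    if (length(i) < 2) next
    bm <- colMeans(x[i, , drop = FALSE])
    bsd <- apply(x[i, , drop = FALSE], 2, stats::sd)
    bsd[bsd == 0] <- 1
    sc <- ifelse(gsd > 0, gsd / bsd, 1)
    x[i, ] <- sweep(sweep(sweep(sweep(x[i, , drop = FALSE], 2, bm, "-"),
                                2, sc, "*"), 2, gm, "+"), 2, 0, "+")
  }
  x
}

#' Adjust pseudobulk expression for batch, known and hidden covariates
#'
#' Stage 1 removes batch structure: per gene and batch, values are centered
#' and rescaled to the pooled mean/variance (`meanvar`), or shrunk with a
#' parametric empirical-Bayes model of batch location/scale before
#' adjustment (`eb`). Stage 2 regresses each gene on the known covariates
#' (age, sex, RIN, PMI), extracts the top `n_hidden` principal components of
#' the residual matrix as surrogate factors, and returns the residuals of
#' expression on known covariates plus surrogates.
#'
#' `n_hidden` is capped at `subjects - rank(known) - 1` with a warning.
#' Single-batch input makes stage 1 the identity.
#'
#' @param pb a [pseudobulk()] in state `normalized_mean`.
#' @param cov covariate data.frame (`subject_id`, `age`, `sex`, `rin`,
#'   `pmi`, `batch`); every non-missing pseudobulk subject must appear.
#' @param n_hidden number of surrogate factors (default 30).
#' @param batch_mode `"meanvar"` or `"eb"`.
#' @return The adjusted [pseudobulk()] in state `residualized`.
#' @export
adjust_covariates <- function(pb, cov, n_hidden = 30,
                              batch_mode = c("meanvar", "eb")) {
  batch_mode <- match.arg(batch_mode)
  stopifnot(pb$state == "normalized_mean")
  present <- rownames(pb$values)[stats::complete.cases(pb$values)]
  missing_cov <- setdiff(present, cov$subject_id)
  if (length(missing_cov))
    stop("covariates missing for subject(s): ",
         paste(utils::head(missing_cov, 5), collapse = ", "))
  x <- pb$values[present, , drop = FALSE]
  cc <- cov[match(present, cov$subject_id), , drop = FALSE]

  if (length(unique(cc$batch)) > 1) {
    x <- switch(batch_mode,
                meanvar = meanvar_batch_adjust(x, cc$batch),
                eb = eb_batch_adjust(x, cc$batch))
  }

  known <- stats::model.matrix(~ age + sex + rin + pmi, data = cc)
  qk <- qr(known)
  cap <- nrow(x) - qk$rank - 1L
  if (n_hidden > cap) {
    warning("n_hidden reduced from ", n_hidden, " to ", cap)
    n_hidden <- max(cap, 0L)
  }
  res1 <- qr.resid(qk, x)
  design <- known
  if (n_hidden > 0) {
    # correlation-scale PCA: gene-wise standardization keeps high-variance
    # genes (and any single-gene cis effect) from dominating the surrogates
    sds <- apply(res1, 2, stats::sd)
    pc <- stats::prcomp(res1[, sds > 0, drop = FALSE], center = TRUE,
                        scale. = TRUE)
    k <- min(n_hidden, ncol(pc$x))
    design <- cbind(known, pc$x[, seq_len(k), drop = FALSE])
  }
  resid <- qr.resid(qr(design), x)

  out <- matrix(NA_real_, nrow(pb$values), ncol(pb$values),
                dimnames = dimnames(pb$values))
  out[present, ] <- resid
  p2 <- pseudobulk(out, pb$cell_type, state = "normalized_mean")
  p2 <- advance_state(p2, "batch_adjusted")
  advance_state(p2, "residualized")
}

#' Z-scale residualized pseudobulk expression gene-wise
#'
#' Per gene: `(x - mean) / sd` over non-missing subjects (sample SD,
#' denominator n-1), so downstream eQTL effects are in SD-per-allele units.
#' Genes with zero SD are dropped with a logged count.
#'
#' @param pb a [pseudobulk()] in state `residualized`.
#' @return A [pseudobulk()] in state `zscaled`.
#' @export
zscale <- function(pb) {
  stopifnot(pb$state == "residualized")
  x <- pb$values
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  drop <- is.na(sds) | sds == 0
  if (any(drop))
    message("zscale: dropped ", sum(drop), " constant gene(s)")
  x <- x[, !drop, drop = FALSE]
  x <- scale(x, center = TRUE, scale = TRUE)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  out <- pseudobulk(x, pb$cell_type, state = "residualized")
  advance_state(out, "zscaled")
}
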