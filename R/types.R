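#' Construct a variant table
#'
#' A variant table holds one row per biallelic variant with its genomic
#' coordinates, the counted (effect) allele `a1`, the other allele `a2`, and
#' the effect-allele frequency `eaf`. Positions are 1-based (VCF convention)
#' throughout the package and intervals are inclusive on both ends.
#'
#' @param id character variant identifiers (unique).
#' @param chrom character chromosome labels.
#' @param pos 1-based integer positions.
#' @param a1,a2 effect and other allele (single-character strings; `a1 != a2`).
#' @param eaf effect-allele frequency in `[0, 1]`.
#' @return A `data.frame` with class `"variant_table"`.
#' @export
variant_table <- function(id, chrom, pos, a1, a2, eaf) {
  v <- data.frame(id = as.character(id), chrom = as.character(chrom),
                  pos = as.integer(pos), a1 = as.character(a1),
                  a2 = as.character(a2), eaf = as.numeric(eaf),
                  stringsAsFactors = FALSE)
  validate_variant_table(v)
  class(v) <- c("variant_table", "data.frame")
  v
}

validate_variant_table <- function(v) {
  stopifnot(is.data.frame(v),
            all(c("id", "chrom", "pos", "a1", "a2", "eaf") %in% names(v)))
  if (anyDuplicated(v$id))
    stop("duplicated variant id(s): ",
         paste(unique(v$id[duplicated(v$id)]), collapse = ", "))
  if (any(v$pos < 1L, na.rm = TRUE)) stop("variant positions must be >= 1")
  if (any(v$a1 == v$a2)) stop("a1 must differ from a2")
  bad <- !is.na(v$eaf) & (v$eaf < 0 | v$eaf > 1)
  if (any(bad)) stop("eaf outside [0, 1]")
  invisible(v)
}

#' Construct a genotype matrix
#'
#' Dosages of the `a1` allele (0--2, possibly fractional for imputed data,
#' `NA` where missing) for `subjects` rows by `variants` columns. Missing
#' dosages are never imputed here; downstream regressions exclude them
#' pairwise.
#'
#' @param dosage numeric matrix, subjects x variants, values in `[0, 2]` or
#'   `NA`.
#' @param variants a [variant_table()] describing the columns.
#' @param subjects subject identifiers (default: rownames of `dosage`).
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `dosage`, `variants`, `subjects`.
#' @export
genotype_matrix <- function(dosage, variants, subjects = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(subjects)) stop("subject identifiers are required")
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("duplicated subject identifier(s)")
  validate_variant_table(variants)
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " columns but variants has ",
         nrow(variants), " rows")
  if (nrow(dosage) != length(subjects))
    stop("dosage has ", nrow(dosage), " rows but ", length(subjects),
         " subjects given")
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1e-8 || rng[2] > 2 + 1e-8))
    stop("dosages must lie in [0, 2]")
  dimnames(dosage) <- list(subjects, variants$id)
  structure(list(dosage = dosage, variants = variants, subjects = subjects),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$subjects), " subjects x ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix by variant id
#' @param gm a [genotype_matrix()].
#' @param ids variant ids to keep (order preserved).
#' @return A `genotype_matrix` restricted to `ids`.
#' @export
subset_variants <- function(gm, ids) {
  keep <- match(ids, gm$variants$id)
  if (anyNA(keep)) stop("unknown variant id(s): ",
                        paste(ids[is.na(keep)], collapse = ", "))
  v <- gm$variants[keep, , drop = FALSE]
  rownames(v) <- NULL
  class(v) <- c("variant_table", "data.frame")
  structure(list(dosage = gm$dosage[, keep, drop = FALSE], variants = v,
                 subjects = gm$subjects), class = "genotype_matrix")
}

#' Construct a single-cell UMI count container
#'
#' @param counts cells x genes matrix of non-negative integer UMI counts
#'   (dense or `Matrix` sparse).
#' @param cell_meta `data.frame` with columns `cell_id`, `subject_id`,
#'   `cell_type`, `batch`; one row per row of `counts`.
#' @param gene_ids character gene identifiers for the columns.
#' @return An object of class `"cell_counts"`.
#' @export
cell_counts <- function(counts, cell_meta, gene_ids = colnames(counts)) {
  need <- c("cell_id", "subject_id", "cell_type", "batch")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss)) stop("cell_meta missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(cell_meta) != nrow(counts))
    stop("cell_meta has ", nrow(cell_meta), " rows but counts has ",
         nrow(counts), " cells")
  if (is.null(gene_ids)) stop("gene identifiers are required")
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids length does not match counts columns")
  if (any(is.na(cell_meta$subject_id)) || any(is.na(cell_meta$cell_type)) ||
      any(is.na(cell_meta$batch)))
    stop("every cell needs a subject, cell type, and batch")
  mn <- min(counts)
  if (mn < 0) stop("counts must be non-negative")
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_ids = as.character(gene_ids)),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat("<cell_counts> ", nrow(x$cell_meta), " cells x ", length(x$gene_ids),
      " genes; ", length(unique(x$cell_meta$cell_type)), " cell types, ",
      length(unique(x$cell_meta$subject_id)), " subjects\n", sep = "")
  invisible(x)
}

#' Construct a summary-statistics table
#'
#' The lingua franca of the meta-analysis, colocalization, and SMR stages:
#' one row per variant with effect `beta` on the `a1` scale, its standard
#' error, two-sided p-value, effect-allele frequency and sample size.
#'
#' @param df data.frame with columns `snp`, `a1`, `a2`, `freq`, `beta`, `se`,
#'   `p`, `n` and optionally `chr`, `bp`.
#' @param trait label for the trait the statistics describe.
#' @return `df` with class `"sumstats"` and attribute `trait`.
#' @export
sumstats <- function(df, trait = "trait") {
  need <- c("snp", "a1", "a2", "freq", "beta", "se", "p", "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("summary statistics missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  ok <- !is.na(df$se) & df$se > 0 & !is.na(df$p) & df$p > 0 & df$p <= 1
  if (any(!ok)) {
    message("sumstats: dropped ", sum(!ok),
            " row(s) with se <= 0 or p outside (0, 1]")
  }
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "trait") <- trait
  attr(df, "n_dropped") <- sum(!ok)
  class(df) <- c("sumstats", "data.frame")
  df
}

#' Per-cell-type pseudobulk expression
#'
#' Holds a subjects x genes matrix for one cell type together with a
#' processing-state flag. States advance strictly in the order
#' `normalized_mean` -> `batch_adjusted` -> `residualized` -> `zscaled`.
#'
#' @param values subjects x genes numeric matrix (rownames = subjects,
#'   colnames = genes). Rows may be all-`NA` for subjects below the cell
#'   floor.
#' @param cell_type the cell type label.
#' @param state processing state.
#' @return An object of class `"pseudobulk"`.
#' @export
pseudobulk <- function(values, cell_type,
                       state = c("normalized_mean", "batch_adjusted",
                                 "residualized", "zscaled")) {
  state <- match.arg(state)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry subject rownames and gene colnames")
  structure(list(cell_type = cell_type, values = values, state = state),
            class = "pseudobulk")
}

pb_states <- c("normalized_mean", "batch_adjusted", "residualized", "zscaled")

advance_state <- function(pb, to) {
  from <- match(pb$state, pb_states)
  dest <- match(to, pb_states)
  if (is.na(dest) || dest != from + 1L)
    stop("invalid pseudobulk state transition: ", pb$state, " -> ", to)
  pb$state <- to
  pb
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("<pseudobulk:", x$cell_type, "> ", nrow(x$values), " subjects x ",
      ncol(x$values), " genes [", x$state, "]\n", sep = "")
  invisible(x)
}
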