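#' Read genotype dosages
#'
#' Reads a VCF (v4.x) or a dosage TSV into a [genotype_matrix()]. For VCF
#' input the ALT allele becomes the counted allele `a1`: `DS` is passed
#' through when present, otherwise `GT` is converted to the ALT-allele count.
#' Missing genotypes stay `NA` (they are excluded pairwise downstream, never
#' imputed). Multi-allelic records are rejected and counted in a message.
#'
#' A dosage TSV has a header row of variant ids, a first column of subject
#' ids, and optionally a sidecar `<path>.variants.tsv` (written by
#' [write_genotypes()]) carrying variant metadata.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage_tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message("read_genotypes: rejected ", sum(multi), " multi-allelic record(s)")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic records in ", path)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  if (anyDuplicated(ids))
    stop("duplicated variant id(s) in VCF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"), error = function(e) NULL)
  if (!is.null(gt)) {
    dos <- apply(gt, c(1, 2), gt_to_dosage)
  } else {
    dos <- matrix(NA_real_, nrow(fix), ncol(v@gt) - 1L,
                  dimnames = list(ids, colnames(v@gt)[-1]))
  }
  if (any(grepl("(^|:)DS(:|$)", v@gt[, "FORMAT"]))) {
    dsm <- suppressWarnings(vcfR::extract.gt(v, element = "DS",
                                             as.numeric = TRUE))
    ok <- !is.na(dsm)
    dos[ok] <- dsm[ok]  # imputed dosages take precedence where present
  }
  dos <- t(dos)  # vcfR gives variants x samples
  eaf <- colMeans(dos, na.rm = TRUE) / 2
  vt <- variant_table(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                      a1 = fix$ALT, a2 = fix$REF, eaf = eaf)
  genotype_matrix(dos, vt, subjects = rownames(dos))
}

gt_to_dosage <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  al <- suppressWarnings(as.integer(alleles))
  if (anyNA(al)) stop("malformed GT field: ", g)
  sum(al != 0L)
}

read_genotypes_tsv <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(d) < 2) stop("dosage TSV needs a subject column plus variants: ", path)
  subjects <- as.character(d[[1]])
  dos <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  ids <- colnames(dos)
  if (anyDuplicated(ids)) stop("duplicated variant id(s) in ", path)
  side <- paste0(path, ".variants.tsv")
  if (file.exists(side)) {
    vm <- data.table::fread(side, sep = "\t", header = TRUE, data.table = FALSE)
    vm <- vm[match(ids, vm$id), , drop = FALSE]
    vt <- variant_table(vm$id, vm$chrom, vm$pos, vm$a1, vm$a2, vm$eaf)
  } else {
    vt <- variant_table(ids, chrom = NA_character_, pos = 1L,
                        a1 = "A", a2 = "B",
                        eaf = colMeans(dos, na.rm = TRUE) / 2)
  }
  genotype_matrix(dos, vt, subjects = subjects)
}

#' Write genotype dosages as TSV (plus a variant-metadata sidecar)
#' @param gm a [genotype_matrix()].
#' @param path output path for the dosage TSV; variant metadata goes to
#'   `<path>.variants.tsv`.
#' @export
write_genotypes <- function(gm, path) {
  d <- data.frame(subject_id = gm$subjects, gm$dosage, check.names = FALSE)
  data.table::fwrite(d, path, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(as.data.frame(gm$variants), paste0(path, ".variants.tsv"),
                     sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a sparse UMI count directory
#'
#' Expects `matrix.mtx` (Matrix-Market triplet, rows = cells, cols = genes),
#' `genes.tsv` (column `gene_id`) and `cells.tsv` (columns `cell_id`,
#' `subject_id`, `cell_type`, `batch`), as written by [write_counts()].
#'
#' @param dir directory path.
#' @return A [cell_counts()].
#' @export
read_counts <- function(dir) {
  fm <- file.path(dir, "matrix.mtx")
  fg <- file.path(dir, "genes.tsv")
  fc <- file.path(dir, "cells.tsv")
  for (f in c(fm, fg, fc)) if (!file.exists(f)) stop("missing file: ", f)
  m <- Matrix::readMM(fm)
  genes <- data.table::fread(fg, sep = "\t", header = TRUE, data.table = FALSE)
  cells <- data.table::fread(fc, sep = "\t", header = TRUE, data.table = FALSE)
  if (nrow(genes) != ncol(m))
    stop("dimension mismatch: genes.tsv has ", nrow(genes),
         " rows but matrix.mtx has ", ncol(m), " columns")
  if (nrow(cells) != nrow(m))
    stop("dimension mismatch: cells.tsv has ", nrow(cells),
         " rows but matrix.mtx has ", nrow(m), " rows")
  m <- methods::as(m, "CsparseMatrix")
  rownames(m) <- cells$cell_id
  colnames(m) <- genes$gene_id
  cell_counts(m, cells, genes$gene_id)
}

#' Write a sparse UMI count directory
#' @param cc a [cell_counts()].
#' @param dir output directory (created if needed).
#' @export
write_counts <- function(cc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(cc$counts, "dMatrix"), "TsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  data.table::fwrite(data.frame(gene_id = cc$gene_ids),
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(cc$cell_meta, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE)
  invisible(dir)
}

# column-name synonyms accepted by read_sumstats, GCTA .ma dialect + CHR/BP
sumstats_synonyms <- list(
  snp  = c("snp", "variant_id", "rsid", "id", "markername"),
  chr  = c("chr", "chrom", "chromosome"),
  bp   = c("bp", "pos", "position", "bp_hg38"),
  a1   = c("a1", "effect_allele", "alt"),
  a2   = c("a2", "other_allele", "ref"),
  freq = c("freq", "eaf", "af", "frq", "effect_allele_frequency"),
  beta = c("beta", "b", "effect"),
  se   = c("se", "stderr", "standard_error"),
  p    = c("p", "pval", "p_value", "pvalue"),
  n    = c("n", "samplesize", "n_total")
)

#' Read GWAS/eQTL summary statistics
#'
#' Reads a tab-separated table in the GCTA ".ma"-style dialect
#' (`SNP A1 A2 FREQ BETA SE P N`, plus optional `CHR`/`BP`). Column-name
#' synonyms are matched case-insensitively; `col_map` overrides them. Rows
#' with `se <= 0` or `p` outside `(0, 1]` are dropped with a logged count.
#'
#' @param path file path.
#' @param trait trait label attached to the result.
#' @param col_map optional named list mapping canonical names (`snp`, `a1`,
#'   ...) to the file's column names.
#' @return A [sumstats()] table.
#' @export
read_sumstats <- function(path, trait = basename(path), col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  lowered <- tolower(names(d))
  pick <- function(canon) {
    if (!is.null(col_map[[canon]])) {
      j <- match(tolower(col_map[[canon]]), lowered)
    } else {
      j <- match(sumstats_synonyms[[canon]], lowered)
      j <- j[!is.na(j)][1]
    }
    if (length(j) == 0 || is.na(j)) NA_integer_ else j
  }
  idx <- vapply(names(sumstats_synonyms), pick, integer(1))
  mandatory <- c("snp", "a1", "a2", "freq", "beta", "se", "p", "n")
  miss <- mandatory[is.na(idx[mandatory])]
  if (length(miss))
    stop("summary-statistics file lacks required column(s): ",
         paste(toupper(miss), collapse = ", "),
         " (accepted dialect: SNP A1 A2 FREQ BETA SE P N [CHR BP])")
  out <- data.frame(snp = as.character(d[[idx["snp"]]]),
                    a1 = toupper(as.character(d[[idx["a1"]]])),
                    a2 = toupper(as.character(d[[idx["a2"]]])),
                    freq = as.numeric(d[[idx["freq"]]]),
                    beta = as.numeric(d[[idx["beta"]]]),
                    se = as.numeric(d[[idx["se"]]]),
                    p = as.numeric(d[[idx["p"]]]),
                    n = as.numeric(d[[idx["n"]]]),
                    stringsAsFactors = FALSE)
  if (!is.na(idx["chr"])) out$chr <- as.character(d[[idx["chr"]]])
  if (!is.na(idx["bp"])) out$bp <- as.integer(d[[idx["bp"]]])
  sumstats(out, trait = trait)
}

#' Write summary statistics in the tab-separated dialect read_sumstats reads
#' @param ss a [sumstats()] table.
#' @param path output path.
#' @export
write_sumstats <- function(ss, path) {
  d <- as.data.frame(ss)
  up <- toupper(names(d))
  names(d) <- up
  data.table::fwrite(d, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read gene annotation (gene_id, chrom, start, end, strand; 1-based inclusive)
#' @param path TSV path.
#' @return data.frame of gene annotation.
#' @export
read_gene_annotation <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("gene annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(d$start > d$end)) stop("gene annotation with start > end")
  d$chrom <- as.character(d$chrom)
  d
}

#' Read subject covariates (age, sex, rin, pmi, batch, pathology_score, group)
#' @param path TSV path with a `subject_id` column.
#' @return data.frame, one row per subject.
#' @export
read_covariates <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!"subject_id" %in% names(d)) stop("covariates need a subject_id column")
  if (anyDuplicated(d$subject_id)) stop("duplicated subject_id in covariates")
  if ("pathology_score" %in% names(d) &&
      any(d$pathology_score < 0, na.rm = TRUE))
    stop("pathology_score must be >= 0")
  d
}

#' Read phased per-subject allele counts
#'
#' Columns: `subject_id`, `cell_type`, `variant_id`, `gene_id`, `a1_umis`,
#' `total_umis` with `0 <= a1_umis <= total_umis`.
#' @param path TSV path.
#' @return data.frame of phased allele counts.
#' @export
read_allele_counts <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("subject_id", "cell_type", "variant_id", "gene_id",
            "a1_umis", "total_umis")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("allele counts missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(d$a1_umis < 0 | d$a1_umis > d$total_umis))
    stop("a1_umis must lie in [0, total_umis]")
  d
}

#' Write any result table as tab-separated UTF-8 with a single header line
#' @param df a data.frame.
#' @param path output path.
#' @export
write_table <- function(df, path) {
  data.table::fwrite(as.data.frame(df), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Write/read per-cell-type pseudobulk expression TSV
#'
#' Subjects x genes table with a single comment header line carrying the
#' cell type and processing state, so downstream stages can refuse
#' out-of-order input.
#'
#' @param pb a [pseudobulk()].
#' @param path output path.
#' @export
write_pseudobulk <- function(pb, path) {
  writeLines(sprintf("# cell_type=%s state=%s", pb$cell_type, pb$state), path)
  df <- data.frame(subject_id = rownames(pb$values), pb$values,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE,
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_pseudobulk
#' @return `read_pseudobulk` returns the [pseudobulk()] object.
#' @export
read_pseudobulk <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("cell_type=(\\S+) state=(\\S+)", hdr))[[1]]
  if (length(m) != 3) stop("missing pseudobulk state header in ", path)
  d <- data.table::fread(path, skip = 1, sep = "\t", header = TRUE,
                         data.table = FALSE)
  vals <- as.matrix(d[, -1, drop = FALSE])
  rownames(vals) <- d[[1]]
  pseudobulk(vals, m[2], state = m[3])
}
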