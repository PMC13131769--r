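# readers/writers and allele harmonization

write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "0/0", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "T", "C", ".", "PASS", ".", "GT:DS",
          "0/1:1.73", "0/0:0.12", "./.:.", sep = "\t"),
    paste("1", "300", "rs3", "G", "A,C", ".", "PASS", ".", "GT",
          "0/1", "0/0", "1/1", sep = "\t"))
  writeLines(lines, path)
  path
}

test_that("VCF genotypes: GT counts ALT alleles, DS passes through, multi-allelics rejected", {
  f <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"))
  expect_message(gm <- read_genotypes(f), "multi-allelic")
  expect_equal(gm$variants$id, c("rs1", "rs2"))
  expect_equal(gm$variants$a1, c("G", "C"))  # ALT becomes the counted allele
  expect_equal(unname(gm$dosage[, "rs1"]), c(1, 0, 2))
  expect_equal(unname(gm$dosage[, "rs2"]), c(1.73, 0.12, NA))
  expect_equal(gm$subjects, c("S1", "S2", "S3"))
})

test_that("dosage TSV round-trips to an identical matrix with metadata", {
  gm <- toy_genotypes()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, f)
  gm2 <- read_genotypes(f, format = "dosage_tsv")
  expect_equal(unname(gm2$dosage), unname(gm$dosage), ignore_attr = TRUE)
  expect_equal(gm2$subjects, gm$subjects)
  expect_equal(gm2$variants$a1, gm$variants$a1)
  expect_equal(gm2$variants$pos, gm$variants$pos)
})

test_that("genotype container enforces its invariants", {
  gm <- toy_genotypes()
  # column mean / 2 reproduces eaf on complete data
  expect_true(all(abs(colMeans(gm$dosage) / 2 - gm$variants$eaf) <= 0.05))
  expect_error(genotype_matrix(gm$dosage, gm$variants,
                               subjects = rep("S1", nrow(gm$dosage))),
               "duplicated")
  bad <- gm$variants; bad$id[2] <- bad$id[1]
  expect_error(validate_variant_table(bad), "duplicated")
})

test_that("sparse count directories round-trip and catch dimension mismatches", {
  m <- Matrix::sparseMatrix(i = c(1, 1, 2, 3), j = c(1, 2, 2, 1),
                            x = c(5, 1, 2, 7), dims = c(3, 2))
  rownames(m) <- paste0("c", 1:3); colnames(m) <- c("gA", "gB")
  meta <- data.frame(cell_id = paste0("c", 1:3),
                     subject_id = c("S1", "S1", "S2"),
                     cell_type = "GLU", batch = "b1")
  cc <- cell_counts(m, meta, c("gA", "gB"))
  d <- withr::local_tempdir()
  write_counts(cc, d)
  cc2 <- read_counts(d)
  expect_equal(as.matrix(cc2$counts), as.matrix(cc$counts))
  expect_equal(Matrix::nnzero(cc2$counts), 4)
  expect_equal(cc2$cell_meta$subject_id, meta$subject_id)
  # a cell present in metadata but absent from the matrix is a contract error
  writeLines(readLines(file.path(d, "cells.tsv"))[1:3],
             file.path(d, "cells.tsv"))
  expect_error(read_counts(d), "cells.tsv")
  expect_error(cell_counts(m, meta[1:2, ], c("gA", "gB")), "rows")
})

test_that("summary statistics reader enforces the dialect and drops bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tA2\tFREQ\tBETA\tSE\tP\tN",
               "rs1\tA\tG\t0.3\t0.5\t0.25\t0.0455\t1000",
               "rs2\tT\tC\t0.2\t0.1\t0\t0.5\t1000",
               "rs3\tC\tG\t0.4\t-0.2\t0.1\t1.5\t1000"), f)
  expect_message(ss <- read_sumstats(f), "dropped 2")
  expect_equal(ss$snp, "rs1")
  expect_equal(attr(ss, "n_dropped"), 2)
  # |z| = 2.0 consistent with p = 0.0455 under the two-sided normal
  z <- abs(ss$beta / ss$se)
  expect_equal(2 * pnorm(-z), ss$p, tolerance = 0.1)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\teffect_allele\tother_allele\teaf\tb\tstderr\tpval\tn",
               "rs1\tA\tG\t0.3\t0.5\t0.25\t0.0455\t1000"), f2)
  expect_equal(read_sumstats(f2)$beta, 0.5)  # synonym dialect

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tA1\tA2\tBETA\tSE\tP\tN", "rs1\tA\tG\t0.5\t0.2\t0.05\t10"), f3)
  expect_error(read_sumstats(f3), "FREQ")
})

test_that("summary statistics round-trip through the writer", {
  ss <- sumstats(data.frame(snp = c("rs1", "rs2"), chr = "1",
                            bp = c(100L, 200L), a1 = c("A", "T"),
                            a2 = c("G", "C"), freq = c(0.31, 0.22),
                            beta = c(0.512, -0.133), se = c(0.1, 0.21),
                            p = c(3e-7, 0.52), n = c(900, 900)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, f)
  ss2 <- read_sumstats(f)
  for (cl in c("snp", "a1", "a2", "freq", "beta", "se", "p", "n"))
    expect_equal(ss2[[cl]], ss[[cl]])
})

test_that("allele harmonization flips swapped strands and drops the unresolvable", {
  ref <- variant_table(id = c("rs1", "rs2", "rs3"), chrom = "1",
                       pos = c(1L, 2L, 3L), a1 = c("T", "A", "A"),
                       a2 = c("G", "T", "G"), eaf = c(0.3, 0.5, 0.2))
  ss <- sumstats(data.frame(snp = c("rs1", "rs2", "rs3"),
                            a1 = c("G", "A", "A"), a2 = c("T", "T", "C"),
                            freq = c(0.7, 0.5, 0.2), beta = c(0.3, 0.2, 0.1),
                            se = 0.1, p = 0.01, n = 100))
  expect_message(h <- harmonize_alleles(ss, ref), "dropped 1.*1.*0")
  expect_equal(h$snp, "rs1")
  expect_equal(h$beta, -0.3)          # swapped alleles flip the sign
  expect_equal(h$freq, 0.3)
  expect_equal(h$a1, "T")
  # rs2: palindromic A/T at frequency 0.5 -> unresolvable; rs3: {A,C} vs {A,G}
})

test_that("harmonization is an involution on effect signs", {
  ref_fwd <- variant_table(id = paste0("v", 1:4), chrom = "1", pos = 1:4,
                           a1 = c("A", "T", "C", "G"),
                           a2 = c("G", "C", "A", "T"), eaf = rep(0.3, 4))
  ref_rev <- ref_fwd
  ref_rev$a1 <- ref_fwd$a2; ref_rev$a2 <- ref_fwd$a1
  ss <- sumstats(data.frame(snp = paste0("v", 1:4), a1 = ref_fwd$a1,
                            a2 = ref_fwd$a2, freq = c(0.2, 0.3, 0.25, 0.35),
                            beta = c(0.5, -0.2, 0.1, 0), se = 0.1,
                            p = 0.01, n = 50))
  once <- harmonize_alleles(ss, ref_rev)
  twice <- harmonize_alleles(once, ref_fwd)
  expect_equal(twice$beta, ss$beta)
  expect_equal(twice$freq, ss$freq)
})
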