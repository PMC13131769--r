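# variant selection, cis-window OLS mapping, dynamic interactions

test_that("marginal OLS matches the lm oracle including missing dosages", {
  withr::with_seed(1, {
    n <- 80
    X <- matrix(rbinom(n * 6, 2, 0.3), n, 6)
    X[sample(length(X), 25)] <- NA
    y <- rnorm(n)
  })
  fit <- marginal_ols(y, X)
  for (j in 1:6) {
    o <- summary(lm(y ~ X[, j]))$coefficients
    expect_equal(fit$beta[j], o[2, 1], tolerance = 1e-10)
    expect_equal(fit$se[j], o[2, 2], tolerance = 1e-10)
    expect_equal(fit$p[j], o[2, 4], tolerance = 1e-10)
  }
  # p equals the two-sided t tail of t at n-2 df
  expect_equal(fit$p, 2 * pt(-abs(fit$t), fit$n - 2), tolerance = 1e-12)
})

test_that("a perfect allelic series fits exactly", {
  fit <- marginal_ols(c(0, 1, 2, 0, 1, 2), cbind(v = c(0, 1, 2, 0, 1, 2)))
  expect_equal(fit$beta, 1.0)
  expect_lt(fit$se, 1e-7)  # zero residual sum of squares
})

test_that("cis-window membership is inclusive at exactly 1 Mb", {
  ann <- data.frame(gene_id = "g1", chrom = "1", start = 2000000L,
                    end = 2010000L, strand = "+")
  pos <- c(2000000L - 1000000L, 2000000L - 1000001L, 2010000L + 1000000L,
           2010000L + 1000001L)
  withr::with_seed(2, dos <- matrix(rbinom(30 * 4, 2, 0.4), 30, 4))
  vt <- variant_table(paste0("v", 1:4), "1", pos, rep("A", 4), rep("G", 4),
                      colMeans(dos) / 2)
  gm <- genotype_matrix(dos, vt, subjects = sprintf("S%d", 1:30))
  withr::with_seed(3, y <- matrix(rnorm(30), 30, 1,
                                  dimnames = list(gm$subjects, "g1")))
  pb <- pseudobulk(y, "GLU", state = "zscaled")
  rec <- map_cis(pb, gm, ann, min_n = 10)
  expect_setequal(rec$variant_id, c("v1", "v3"))
})

test_that("swapping the counted allele flips beta exactly", {
  gm <- toy_genotypes()
  withr::with_seed(4, y <- matrix(rnorm(60), 60, 1,
                                  dimnames = list(gm$subjects, "g1")))
  ann <- data.frame(gene_id = "g1", chrom = "1", start = 1000L, end = 2000L,
                    strand = "+")
  pb <- pseudobulk(y, "GLU", state = "zscaled")
  rec <- map_cis(pb, gm, ann, min_n = 10)
  swapped <- gm
  swapped$dosage <- 2 - swapped$dosage
  tmp <- swapped$variants$a1
  swapped$variants$a1 <- swapped$variants$a2
  swapped$variants$a2 <- tmp
  rec2 <- map_cis(pb, swapped, ann, min_n = 10)
  expect_equal(rec2$beta, -rec$beta, tolerance = 1e-12)
  expect_equal(rec2$p, rec$p, tolerance = 1e-12)
})

test_that("candidate variants are classed by GWAS significance and LD proxying", {
  gm <- toy_genotypes(n = 200, seed = 5)
  # v1: genome-wide; v2: r2 = 1 proxy of v1; v3: sub-threshold near the lead;
  # v4: MAF below the filter (would otherwise be class 1)
  ss <- sumstats(data.frame(
    snp = c("v1", "v2", "v3", "v4"), chr = "1",
    bp = gm$variants$pos, a1 = gm$variants$a1, a2 = gm$variants$a2,
    freq = gm$variants$eaf, beta = c(0.5, 0.1, 0.2, 0.6),
    se = 0.05, p = c(4e-8, 0.2, 5e-7, 1e-9), n = 5000))
  sel <- select_candidate_variants(ss, gm)
  expect_equal(sel$class[sel$variant_id == "v1"], 1)
  expect_equal(sel$class[sel$variant_id == "v3"], 2)
  expect_equal(sel$class[sel$variant_id == "v2"], 3)
  expect_false("v4" %in% sel$variant_id)
  cnt <- attr(sel, "class_counts")
  expect_equal(unname(cnt["total"]), unname(sum(cnt[1:3])))

  # r2 below 0.4 with every selected variant and p above both gates -> out
  ss2 <- ss; ss2$p <- c(4e-8, 0.2, 0.2, 0.2)
  gm2 <- gm; gm2$dosage[, "v2"] <- rev(gm2$dosage[, "v2"])  # break the LD
  sel2 <- select_candidate_variants(ss2, gm2)
  expect_false("v3" %in% sel2$variant_id)
})

test_that("dynamic interaction recovers an exact product structure", {
  n <- 60
  subj <- sprintf("S%d", 1:n)
  withr::with_seed(6, {
    x <- rbinom(n, 2, 0.4)
    s <- sample(0:4, n, replace = TRUE)
  })
  y <- matrix((x - mean(x)) * (s - mean(s)), n, 1,
              dimnames = list(subj, "g1"))
  vt <- variant_table("v1", "1", 100L, "A", "G", mean(x) / 2)
  gm <- genotype_matrix(cbind(v1 = x), vt, subjects = subj)
  cov <- basic_covariates(subj, score = s)
  pb <- pseudobulk(y, "GLU", state = "residualized")
  pairs <- data.frame(gene_id = "g1", variant_id = "v1")
  rec <- dynamic_interaction(pb, gm, cov, pairs, center = TRUE)
  expect_equal(rec$beta_interaction, 1.0, tolerance = 1e-8)
  expect_true(rec$dynamic)

  # constant pathology score -> warning and empty result
  cov0 <- basic_covariates(subj, score = rep(2, n))
  expect_warning(out <- dynamic_interaction(pb, gm, cov0, pairs), "constant")
  expect_equal(nrow(out), 0)
})

test_that("planted interactions are detected with the right sign", {
  n <- 300
  subj <- sprintf("S%d", 1:n)
  hits <- 0L
  withr::with_seed(7, {
    for (r in 1:20) {
      x <- rbinom(n, 2, 0.4)
      s <- sample(0:4, n, replace = TRUE)
      y <- matrix(0.3 * x * s + rnorm(n), n, 1, dimnames = list(subj, "g1"))
      vt <- variant_table("v1", "1", 100L, "A", "G", mean(x) / 2)
      gm <- genotype_matrix(cbind(v1 = x), vt, subjects = subj)
      cov <- basic_covariates(subj, score = s)
      pb <- pseudobulk(y, "GLU", state = "residualized")
      rec <- dynamic_interaction(pb, gm, cov,
                                 data.frame(gene_id = "g1", variant_id = "v1"))
      if (rec$beta_interaction > 0 && rec$p_interaction < 0.05) hits <- hits + 1L
    }
  })
  expect_gte(hits / 20, 0.9)
})
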