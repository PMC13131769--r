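# synthetic cohort generators: determinism, LD structure, planted effects

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_subjects = 40, n_datasets = 1, n_loci = 2,
                    variants_per_locus = 8, genes_per_locus = 1,
                    cell_types = c("GLU", "Oli"),
                    cells_per_subject_per_type = 5,
                    eqtl_cell_types = "GLU", seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$datasets[[1]]$genotypes$dosage,
                   b$datasets[[1]]$genotypes$dosage)
  expect_identical(as.matrix(a$datasets[[1]]$cells$counts),
                   as.matrix(b$datasets[[1]]$cells$counts))
  expect_identical(a$gwas$beta, b$gwas$beta)
  expect_identical(a$ase, b$ase)
})

test_that("ld_decay = 0 gives independent adjacent variants", {
  cfg <- sim_config(n_subjects = 500, n_loci = 1, variants_per_locus = 40,
                    ld_decay = 0, seed = 3)
  withr::with_seed(3, {
    gm <- simulate_genotypes(cfg)
  })
  r <- diag(cor(gm$dosage)[-1, -ncol(gm$dosage)])
  expect_lt(mean(abs(r)), 3 * 2 / sqrt(500))
})

test_that("ld_decay = 0.9 realizes the target adjacent correlation", {
  cfg <- sim_config(n_subjects = 2000, n_loci = 1, variants_per_locus = 30,
                    ld_decay = 0.9, seed = 4)
  withr::with_seed(4, gm <- simulate_genotypes(cfg))
  r <- diag(cor(gm$dosage)[-1, -ncol(gm$dosage)])
  expect_lt(abs(mean(r) - 0.9), 0.1)
  expect_gt(mean(r^2), 0.64)
  expect_lt(mean(r^2), 0.97)
})

test_that("null GWAS p-values are uniform; shared-causal scenario tops its locus", {
  cfg <- null_config(5, n_subjects = 400, n_loci = 4, variants_per_locus = 50,
                     variant_spacing_bp = 1000, ld_decay = 0, n_datasets = 1,
                     cell_types = "GLU", cells_per_subject_per_type = 2,
                     genes_per_locus = 1)
  co <- simulate_cohort(cfg)
  # 200 independent variants per draw; repeat for >= 2000 draws total
  ps <- co$gwas$p
  withr::with_seed(11, {
    for (i in 1:10) {
      g <- simulate_gwas(cfg, co$pooled_genotypes, co$truth)
      ps <- c(ps, g$p)
    }
  })
  frac <- mean(ps < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(ps)))

  # planted z* = 8: the causal variant attains the locus minimum p in >= 80%
  cfg2 <- sim_config(n_subjects = 600, n_loci = 1, variants_per_locus = 25,
                     gwas_scenario = "shared_causal", gwas_z = 8,
                     n_datasets = 1, cell_types = "GLU",
                     cells_per_subject_per_type = 2, seed = 6)
  co2 <- simulate_cohort(cfg2)
  causal <- co2$truth$gwas$trait_causal[1]
  hits <- 0L
  withr::with_seed(12, {
    for (i in 1:200) {
      g <- simulate_gwas(cfg2, co2$pooled_genotypes, co2$truth)
      if (g$snp[which.min(g$p)] == causal) hits <- hits + 1L
    }
  })
  expect_gte(hits / 200, 0.8)
})

test_that("linked-causal scenario separates trait and expression causal variants", {
  cfg <- sim_config(n_subjects = 500, n_loci = 2, variants_per_locus = 25,
                    gwas_scenario = c("linked_causal", "linked_causal"),
                    n_datasets = 1, cell_types = "GLU",
                    cells_per_subject_per_type = 2, seed = 7)
  co <- simulate_cohort(cfg)
  tg <- co$truth$gwas
  expect_true(all(tg$trait_causal != tg$expr_causal))
  expect_true(all(abs(tg$realized_r2 - cfg$linked_r2_target) < 0.15))
})

test_that("single-nucleus counts recover planted cell-type-specific effects", {
  cfg <- sim_config(n_subjects = 150, n_datasets = 1, n_loci = 2,
                    variants_per_locus = 9, genes_per_locus = 1,
                    cell_types = c("GLU", "Oli"), eqtl_cell_types = "GLU",
                    cells_per_subject_per_type = 15, eqtl_effect = 0.5,
                    seed = 8)
  co <- simulate_cohort(cfg)
  ds <- co$datasets[[1]]
  pbs <- normalize_and_pseudobulk(ds$cells)
  pl <- co$truth$planted_eqtls[1, ]
  betas <- sapply(c("GLU", "Oli"), function(ct) {
    y <- pbs[[ct]]$values[, pl$gene_id]
    x <- ds$genotypes$dosage[rownames(pbs[[ct]]$values), pl$variant_id]
    unname(coef(lm(scale(y) ~ x))[2])
  })
  expect_gt(betas["GLU"], 0.2)      # effect present where planted
  expect_lt(abs(betas["Oli"]), 0.15) # near zero elsewhere
})

test_that("allelic imbalance mirrors planted effects; homozygotes emit no rows", {
  cfg <- sim_config(n_subjects = 250, n_datasets = 1, n_loci = 4,
                    variants_per_locus = 9, genes_per_locus = 1,
                    cell_types = "GLU", eqtl_cell_types = "GLU",
                    cells_per_subject_per_type = 2, eqtl_effect = 0.6,
                    ase_mean_umis = 60, seed = 9)
  co <- simulate_cohort(cfg)
  gt <- co$datasets[[1]]$genotypes
  dos <- gt$dosage[cbind(match(co$ase$subject_id, gt$subjects),
                         match(co$ase$variant_id, gt$variants$id))]
  expect_true(all(dos == 1))  # only heterozygotes are informative

  # null variants: pooled a1 fraction is 0.5 within 3 SE
  pl <- co$truth$planted_eqtls
  null_rows <- co$ase[!co$ase$gene_id %in% pl$gene_id, ]
  frac <- sum(null_rows$a1_umis) / sum(null_rows$total_umis)
  se <- sqrt(0.25 / sum(null_rows$total_umis)) * 2  # overdispersion margin
  expect_lt(abs(frac - 0.5), 3 * se + 0.02)

  # planted variants: fitted imbalance sign matches the planted sign
  agg <- pseudobulk_ase(co$ase)
  res <- ase_test_all(agg)
  res <- res[res$gene_id %in% pl$gene_id & res$total_umis >= 200, ]
  expect_gte(mean(res$log_odds > 0), 0.9)
})

test_that("GWAS and eQTL evidence co-vary across loci (mediation structure)", {
  cfg <- sim_config(n_subjects = 250, n_datasets = 2, n_loci = 6,
                    variants_per_locus = 9, genes_per_locus = 1,
                    cell_types = "GLU", eqtl_cell_types = "GLU",
                    cells_per_subject_per_type = 10,
                    gwas_scenario = rep(c("shared_causal", "null"), 3),
                    seed = 10)
  co <- simulate_cohort(cfg)
  mid <- cfg$variants_per_locus %/% 2 + 1
  z_gwas <- z_eqtl <- numeric(cfg$n_loci)
  pbs <- lapply(co$datasets, function(d)
    normalize_and_pseudobulk(d$cells)[["GLU"]])
  for (l in seq_len(cfg$n_loci)) {
    v <- sprintf("rsL%d_%02d", l, mid)
    g <- sprintf("gene_L%d_1", l)
    z_gwas[l] <- abs(co$gwas$beta / co$gwas$se)[match(v, co$gwas$snp)]
    zs <- sapply(seq_along(pbs), function(d) {
      y <- scale(pbs[[d]]$values[, g])
      x <- co$datasets[[d]]$genotypes$dosage[rownames(pbs[[d]]$values), v]
      summary(lm(y ~ x))$coefficients[2, 3]
    })
    z_eqtl[l] <- mean(abs(zs))
  }
  expect_gt(cor(z_gwas, z_eqtl), 0)
})
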