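# counts-per-10k normalization, pseudobulking, covariate adjustment, z-scaling

test_that("normalization and pseudobulk means follow their definitions", {
  counts <- Matrix::Matrix(rbind(c(5, 495), c(10, 90), c(5, 95)), sparse = TRUE)
  rownames(counts) <- paste0("c", 1:3); colnames(counts) <- c("gA", "gB")
  meta <- data.frame(cell_id = paste0("c", 1:3),
                     subject_id = c("S1", "S2", "S2"),
                     cell_type = "GLU", batch = "b1")
  cc <- cell_counts(counts, meta, c("gA", "gB"))
  pb <- normalize_and_pseudobulk(cc, min_cells = 1)[["GLU"]]
  # one cell, count 5 of total 500 -> 100; single-cell subject = that cell
  expect_equal(pb$values["S1", "gA"], 100)
  # S2: two cells normalized to 1000 and 500 -> mean 750
  expect_equal(pb$values["S2", "gA"], 750)
  expect_equal(pb$state, "normalized_mean")
})

test_that("subjects below the cell floor become missing; zero-UMI cells are excluded", {
  counts <- Matrix::Matrix(rbind(c(2, 8), c(3, 7), c(1, 9), c(0, 0)),
                           sparse = TRUE)
  rownames(counts) <- paste0("c", 1:4); colnames(counts) <- c("gA", "gB")
  meta <- data.frame(cell_id = paste0("c", 1:4),
                     subject_id = c("S1", "S1", "S2", "S3"),
                     cell_type = "GLU", batch = "b1")
  cc <- cell_counts(counts, meta, c("gA", "gB"))
  expect_message(pbs <- normalize_and_pseudobulk(cc, min_cells = 2),
                 "zero total UMIs")
  pb <- pbs[["GLU"]]
  expect_false(anyNA(pb$values["S1", ]))
  expect_true(all(is.na(pb$values["S2", ])))  # min_cells - 1 cells
  expect_true(all(is.na(pb$values["S3", ])))  # only a zero-UMI cell
})

test_that("a constant batch shift is removed and age-linear expression residualizes to zero", {
  n <- 40
  subj <- sprintf("S%d", 1:n)
  # constant known covariates so stage 2 only removes the grand mean and the
  # batch contrast isolates stage 1
  cov <- data.frame(subject_id = subj, age = 70, sex = 0, rin = 8, pmi = 5,
                    batch = rep(c("b1", "b2"), each = n / 2),
                    pathology_score = 0, group = "PD")
  withr::with_seed(1, base <- matrix(rnorm(n * 6), n, 6))
  shifted <- base + 5 * (cov$batch == "b2")
  pb <- as_pb(shifted)
  rownames(pb$values) <- subj
  adj <- adjust_covariates(pb, cov, n_hidden = 0)
  for (j in 1:6) {
    m1 <- mean(adj$values[cov$batch == "b1", j])
    m2 <- mean(adj$values[cov$batch == "b2", j])
    expect_lt(abs(m1 - m2), 1e-8)
  }
  expect_equal(adj$state, "residualized")

  # expression exactly linear in age -> residuals vanish
  lin <- matrix(rep(2 * cov$age - 3, 4), n, 4)
  pb2 <- as_pb(lin); rownames(pb2$values) <- subj
  adj2 <- adjust_covariates(pb2, basic_covariates(subj), n_hidden = 0)
  expect_lt(max(abs(adj2$values)), 1e-8)
})

test_that("empirical-Bayes batch mode also removes batch location", {
  n <- 60
  subj <- sprintf("S%d", 1:n)
  cov <- basic_covariates(subj, batch = rep(c("b1", "b2", "b3"), each = n / 3))
  withr::with_seed(2, base <- matrix(rnorm(n * 8), n, 8))
  shifted <- base + 3 * (cov$batch == "b2") - 2 * (cov$batch == "b3")
  pb <- as_pb(shifted); rownames(pb$values) <- subj
  adj <- adjust_covariates(pb, cov, n_hidden = 0, batch_mode = "eb")
  for (j in 1:8) {
    raw <- tapply(shifted[, j], cov$batch, mean)
    mm <- tapply(adj$values[, j], cov$batch, mean)
    # empirical-Bayes shrinkage removes most of the planted location; a
    # shrinkage residual of order the location-noise SD remains by design
    expect_lt(max(mm) - min(mm), 0.25 * (max(raw) - min(raw)))
  }
  # single batch: stage 1 is the identity (residualization still applies)
  cov1 <- basic_covariates(subj)
  a1 <- adjust_covariates(pb, cov1, n_hidden = 0, batch_mode = "meanvar")
  a2 <- adjust_covariates(pb, cov1, n_hidden = 0, batch_mode = "eb")
  expect_equal(a1$values, a2$values)
})

test_that("a planted hidden factor is absorbed by the surrogate factors", {
  n <- 120; g <- 40
  withr::with_seed(3, {
    fac <- rnorm(n)
    load <- c(runif(g / 2, 1, 2), rep(0, g / 2))
    x <- outer(fac, load) + matrix(rnorm(n * g, sd = 0.5), n, g)
  })
  pb <- as_pb(x)
  cov <- basic_covariates(rownames(pb$values))
  adj <- adjust_covariates(pb, cov, n_hidden = 1)
  cors <- abs(cor(adj$values, fac))
  expect_lt(max(cors[seq_len(g / 2)]), 0.1)
  # and n_hidden above the subject cap is reduced with a warning
  expect_warning(adjust_covariates(pb, cov, n_hidden = n + 5), "reduced")
})

test_that("adjustment preserves genotype contrasts when covariates are independent", {
  n <- 150
  withr::with_seed(4, {
    x <- rbinom(n, 2, 0.4)
    y <- 0.5 * x + rnorm(n)
    mat <- cbind(y, matrix(rnorm(n * 9), n, 9))
  })
  pb <- as_pb(mat)
  subj <- rownames(pb$values)
  cov <- basic_covariates(subj, batch = rep(c("b1", "b2"), length.out = n))
  adj <- adjust_covariates(pb, cov, n_hidden = 2)
  fit <- summary(lm(adj$values[, 1] ~ x))$coefficients
  expect_lt(abs(fit[2, 1] - 0.5), 2 * fit[2, 2])
})

test_that("z-scaling standardizes genes and drops constants", {
  pb <- as_pb(cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20)),
              state = "residualized")
  expect_message(z <- zscale(pb), "1 constant gene")
  expect_equal(unname(z$values[, "a"]), c(-1, 0, 1))
  expect_false("b" %in% colnames(z$values))
  expect_true(all(abs(colMeans(z$values)) < 1e-8))
  expect_true(all(abs(apply(z$values, 2, sd) - 1) < 1e-8))
  expect_equal(z$state, "zscaled")
  # state transitions only advance in order
  expect_error(zscale(z), "residualized")
  expect_error(adjust_covariates(z, basic_covariates(rownames(z$values))),
               "normalized_mean")
})

test_that("pseudobulk TSVs round-trip with their state tag", {
  pb <- as_pb(matrix(rnorm(12), 4, 3), cell_type = "Oli",
              state = "residualized")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pseudobulk(pb, f)
  pb2 <- read_pseudobulk(f)
  expect_equal(pb2$values, pb$values, tolerance = 1e-12)
  expect_equal(pb2$cell_type, "Oli")
  expect_equal(pb2$state, "residualized")
  # the state survives, so z-scaling is accepted and re-reading blocked input
  expect_s3_class(zscale(pb2), "pseudobulk")
})
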