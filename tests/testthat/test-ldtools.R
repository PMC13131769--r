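# LD matrices, greedy clumping, chunk assignment, pi1

test_that("LD correlations behave on duplicated and independent columns", {
  gm <- toy_genotypes(n = 2000, seed = 1)
  r <- ld_r(gm, c("v1", "v2", "v3"))
  expect_equal(diag(r), c(v1 = 1, v2 = 1, v3 = 1))
  expect_equal(r["v1", "v2"], 1)            # duplicated column
  expect_lt(abs(r["v1", "v3"]), 0.07)       # independent at n = 2000
  expect_equal(r, t(r))
  expect_error(ld_r(gm, "v1"), "at least 2")
})

make_ld <- function(ids, r2) {
  # build a symmetric signed-r matrix from an r2 specification list
  m <- diag(length(ids)); dimnames(m) <- list(ids, ids)
  for (sp in r2) m[sp[[1]], sp[[2]]] <- m[sp[[2]], sp[[1]]] <- sqrt(sp[[3]])
  m
}

test_that("greedy clumping follows p-value order, LD and distance gates", {
  ids <- c("a", "b", "c")
  ld <- make_ld(ids, list(list("a", "b", 0.5), list("a", "c", 0.05),
                          list("b", "c", 0.05)))
  st <- data.frame(snp = ids, p = c(1e-10, 1e-9, 1e-8), chr = "1",
                   bp = c(1e6, 1.1e6, 1.2e6))
  cl <- clump(st, ld, p1 = 1e-5, p2 = 1e-5)
  expect_equal(length(unique(cl$chunk_id)), 2)
  expect_setequal(cl$member[cl$lead == "a"], c("a", "b"))
  expect_equal(cl$member[cl$lead == "c"], "c")

  # single passing variant forms a singleton clump
  one <- clump(st[1, ], ld, p1 = 1e-5, p2 = 1e-5)
  expect_equal(nrow(one), 1)
  # no variant passes p1 -> empty
  expect_equal(nrow(clump(st, ld, p1 = 1e-20, p2 = 1e-20)), 0)

  # high LD but 501 kb away forms its own clump
  st2 <- data.frame(snp = c("a", "b"), p = c(1e-10, 1e-9), chr = "1",
                    bp = c(1e6, 1e6 + 501000))
  ld2 <- make_ld(c("a", "b"), list(list("a", "b", 0.9)))
  cl2 <- clump(st2, ld2, p1 = 1e-5, p2 = 1e-5)
  expect_equal(length(unique(cl2$chunk_id)), 2)
})

test_that("clumping is order-independent and matches the brute-force oracle", {
  withr::with_seed(2, {
    for (r in 1:15) {
      m <- sample(4:10, 1)
      ids <- paste0("s", seq_len(m))
      dos <- matrix(rbinom(400 * m, 2, runif(m, 0.1, 0.5)), 400, m,
                    byrow = TRUE)
      dos <- dos + rbinom(400 * m, 1, 0.1)  # jitter; keep in [0,2]
      dos[dos > 2] <- 2
      colnames(dos) <- ids
      vt <- variant_table(ids, "1", sort(sample.int(8e5, m)),
                          rep("A", m), rep("G", m), colMeans(dos) / 2)
      gm <- genotype_matrix(dos, vt, subjects = sprintf("S%d", 1:400))
      ld <- ld_r(gm)
      st <- data.frame(snp = ids, p = 10^-runif(m, 0, 12), chr = "1",
                       bp = vt$pos)
      cl <- clump(st, ld, p1 = 1e-2, p2 = 1e-1, r2_thresh = 0.2, kb = 400)
      oracle <- clump_oracle(st, ld, p1 = 1e-2, p2 = 1e-1,
                             r2_thresh = 0.2, kb = 400)
      got <- lapply(split(cl$member, cl$chunk_id), sort)
      expect_equal(length(got), length(oracle))
      for (i in seq_along(oracle)) {
        lead_i <- oracle[[i]]$lead
        expect_equal(sort(cl$member[cl$lead == lead_i]), oracle[[i]]$members)
      }
      # permuting the input rows changes nothing
      perm <- sample(m)
      cl_p <- clump(st[perm, ], ld, p1 = 1e-2, p2 = 1e-1,
                    r2_thresh = 0.2, kb = 400)
      expect_equal(cl_p[order(cl_p$member), c("lead", "member")],
                   cl[order(cl$member), c("lead", "member")],
                   ignore_attr = TRUE)
      # partition: no variant in two clumps; leads minimize p within clump
      expect_false(anyDuplicated(cl$member) > 0)
      for (ch in unique(cl$chunk_id)) {
        sub <- cl[cl$chunk_id == ch, ]
        expect_lte(st$p[st$snp == sub$lead[1]], min(sub$p))
      }
    }
  })
})

test_that("chunk assignment unifies cell types and matches exhaustive lookup", {
  ids <- c("s1", "s2", "s3", "s4", "s5")
  ld <- make_ld(ids, list(list("s1", "s2", 0.8), list("s3", "s4", 0.05),
                          list("s1", "s3", 0.05)))
  st <- data.frame(snp = ids, p = c(1e-9, 1e-8, 1e-9, 0.5, 1e-7),
                   chr = "1", bp = c(1, 2, 3, 4, 5) * 1e5)
  cl <- clump(st, ld, p1 = 1e-6, p2 = 1e-6)
  rec <- data.frame(gene_id = rep(c("gA", "gB"), each = 3),
                    variant_id = c("s1", "s2", "s5", "s3", "s5", "s4"),
                    cell_type = c("GLU", "Oli", "GLU", "GLU", "Oli", "GLU"),
                    p_re2 = c(1e-9, 1e-8, 1e-7, 1e-9, 1e-7, 0.5))
  asg <- assign_to_chunks(rec, cl, threshold = 1e-6)
  # same chunk for the two cell types sharing correlated eSNPs
  ch_s1 <- asg$records$chunk_id[asg$records$variant_id == "s1"][1]
  ch_s2 <- asg$records$chunk_id[asg$records$variant_id == "s2"][1]
  expect_equal(ch_s1, ch_s2)
  # r2 = 0.05 pair lands in distinct chunks
  ch_s3 <- asg$records$chunk_id[asg$records$variant_id == "s3"][1]
  expect_false(identical(ch_s1, ch_s3))
  # detection flags equal the exhaustive definition
  for (i in seq_len(nrow(asg$detection))) {
    d <- asg$detection[i, ]
    members <- cl$member[cl$chunk_id == d$chunk_id]
    manual <- any(rec$p_re2[rec$gene_id == d$gene_id &
                              rec$cell_type == d$cell_type &
                              rec$variant_id %in% members] <= 1e-6)
    expect_equal(d$detected, manual)
  }
  # s4 failed p2 and joined no clump -> NA chunk for its record
  expect_true(is.na(asg$records$chunk_id[asg$records$variant_id == "s4"]))
})

test_that("pi1 estimates the non-null fraction", {
  withr::with_seed(5, {
    expect_lt(pi1(runif(10000)), 0.03)
    expect_equal(pi1(rep(1e-10, 100)), 1)
    mix <- c(pmax(rbeta(3000, 0.05, 10), 1e-12), runif(7000))
    expect_lt(abs(pi1(mix) - 0.30), 0.04)
  })
  expect_error(pi1(c(0.5, 0)), "0")
})
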