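# shared fixtures and independent oracles, built in code at test time

# a small genotype matrix with hand-controlled LD structure:
# v1/v2 duplicated (r2 = 1), v3 independent, v4 rare
toy_genotypes <- function(n = 60, seed = 42) {
  withr::with_seed(seed, {
    v1 <- rbinom(n, 2, 0.4)
    v3 <- rbinom(n, 2, 0.3)
    v4 <- rbinom(n, 2, 0.02)
    dos <- cbind(v1 = v1, v2 = v1, v3 = v3, v4 = v4)
    vt <- variant_table(id = colnames(dos), chrom = "1",
                        pos = c(500L, 1500L, 2500L, 3500L),
                        a1 = c("A", "T", "C", "G"),
                        a2 = c("G", "C", "A", "T"),
                        eaf = colMeans(dos) / 2)
    genotype_matrix(dos, vt, subjects = sprintf("S%d", seq_len(n)))
  })
}

# pseudobulk object straight from a matrix, at a chosen state
as_pb <- function(values, cell_type = "GLU", state = "normalized_mean") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("g%d", seq_len(ncol(values)))
  pseudobulk(values, cell_type, state = state)
}

basic_covariates <- function(subjects, batch = "b1", score = NULL) {
  n <- length(subjects)
  data.frame(subject_id = subjects,
             age = seq(60, 90, length.out = n),
             sex = rep_len(0:1, n),
             rin = rep_len(c(7, 8, 9), n),
             pmi = rep_len(c(4, 6, 8), n),
             batch = rep_len(batch, n),
             pathology_score = if (is.null(score)) rep_len(0:4, n) else score,
             group = "PD",
             stringsAsFactors = FALSE)
}

# independent greedy-clumping oracle: naive loops, no shared code with clump()
clump_oracle <- function(stats, ld, p1, p2, r2_thresh = 0.1, kb = 500) {
  s <- stats[order(stats$p, stats$bp, stats$snp), , drop = FALSE]
  assigned <- character(0)
  out <- list()
  repeat {
    rem <- s[!s$snp %in% assigned & s$p <= p1, , drop = FALSE]
    if (!nrow(rem)) break
    lead <- rem$snp[1]
    lead_bp <- rem$bp[1]; lead_chr <- rem$chr[1]
    members <- lead
    for (v in setdiff(s$snp, c(assigned, lead))) {
      row <- s[s$snp == v, ]
      if (row$p <= p2 && row$chr == lead_chr &&
          abs(row$bp - lead_bp) <= kb * 1000 &&
          ld[lead, v]^2 >= r2_thresh) members <- c(members, v)
    }
    assigned <- c(assigned, members)
    out[[length(out) + 1]] <- list(lead = lead, members = sort(members))
  }
  out
}

# small all-null simulation config (no planted effects, null GWAS everywhere)
null_config <- function(seed, ...) {
  none <- data.frame(gene_id = character(), variant_id = character(),
                     cell_types = character(), effect = numeric())
  args <- list(...)
  args$seed <- seed
  args$planted_eqtls <- none
  cfg <- do.call(sim_config, args)
  cfg$gwas_scenario <- rep("null", cfg$n_loci)
  cfg
}
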