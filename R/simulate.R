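#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by every generator: cohort sizes,
#' LD structure, cell-type panel, planted cis effects, GWAS scenarios, and
#' allele-specific-expression coupling. Defaults describe a three-dataset
#' brain single-nucleus cohort (400 subjects each, nine cell types) with
#' eight GWAS loci of 25 variants; see the methods vignette for the
#' reasoning behind each default.
#'
#' @param n_subjects subjects per dataset.
#' @param n_datasets number of independent single-nucleus datasets.
#' @param n_loci number of GWAS loci (each on its own chromosome).
#' @param variants_per_locus variants per locus.
#' @param variant_spacing_bp spacing between adjacent variants (bp).
#' @param maf_range range the per-locus minor-allele frequency is drawn from
#'   (variants within a locus jitter by at most 0.01 around the locus value,
#'   as strong LD forces near-identical frequencies).
#' @param ld_decay target correlation between adjacent variants' haplotypes
#'   (the latent AR(1) correlation is calibrated so the realized binary
#'   haplotype correlation matches this value).
#' @param genes_per_locus genes annotated per locus (the first carries any
#'   planted effect; the rest are null genes).
#' @param cell_types character vector of cell-type labels.
#' @param cells_per_subject_per_type nuclei simulated per subject and type.
#' @param nb_dispersion negative-binomial size parameter of UMI counts.
#' @param libsize_sdlog sdlog of the log-normal per-cell library-size factor.
#' @param baseline_log_mean range of per-gene baseline log mean UMI counts.
#' @param n_batches,batch_sd library batches per dataset and the sd of the
#'   per-batch, per-gene log-mean shift.
#' @param planted_eqtls `NULL` for the default planting (one eQTL per
#'   non-null locus, effect `eqtl_effect` on the log-mean scale, active in
#'   `eqtl_cell_types`), or a data.frame with columns `gene_id`,
#'   `variant_id`, `cell_types` (comma-separated, or `"all"`), `effect`.
#' @param eqtl_effect default planted allelic effect on the log-mean scale.
#' @param eqtl_cell_types cell types the default planting is active in.
#' @param gwas_scenario `NULL` for the default (half the loci
#'   `shared_causal`, a quarter `linked_causal`, a quarter `null`) or a
#'   character vector of length `n_loci`.
#' @param gwas_z causal-variant z-score planted in the GWAS.
#' @param gwas_n GWAS effective sample size.
#' @param linked_r2_target LD r2 between the expression and trait causal
#'   variants under the `linked_causal` scenario.
#' @param ase_kappa slope linking the planted log-mean eQTL effect to the
#'   allelic log-odds (logit mu = kappa * effect).
#' @param ase_overdispersion beta-binomial overdispersion of allele counts.
#' @param ase_mean_umis mean phased UMIs per subject, cell type and variant.
#' @param interaction_effects `NULL` or a data.frame with columns `gene_id`,
#'   `variant_id`, `cell_type`, `effect` (genotype x pathology interaction on
#'   the log-mean scale).
#' @param seed integer seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 400,
                       n_datasets = 3,
                       n_loci = 8,
                       variants_per_locus = 25,
                       variant_spacing_bp = 4000,
                       maf_range = c(0.15, 0.45),
                       ld_decay = 0.8,
                       genes_per_locus = 2,
                       cell_types = c("GLU", "GABA", "DA", "Oli", "OPCs",
                                      "Ast", "Mic", "End", "Peri"),
                       cells_per_subject_per_type = 20,
                       nb_dispersion = 2,
                       libsize_sdlog = 0.3,
                       baseline_log_mean = log(c(0.5, 3)),
                       n_batches = 2,
                       batch_sd = 0.15,
                       planted_eqtls = NULL,
                       eqtl_effect = 0.5,
                       eqtl_cell_types = c("GLU", "GABA", "DA", "Oli"),
                       gwas_scenario = NULL,
                       gwas_z = 8,
                       gwas_n = 50000,
                       linked_r2_target = 0.25,
                       ase_kappa = 1,
                       ase_overdispersion = 0.05,
                       ase_mean_umis = 40,
                       interaction_effects = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_subjects > 0, n_datasets > 0, n_loci > 0,
            variants_per_locus > 1, genes_per_locus >= 1,
            ld_decay >= 0, ld_decay < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            cells_per_subject_per_type > 0, nb_dispersion > 0,
            gwas_n > 0, ase_overdispersion >= 0, ase_mean_umis > 0)
  if (is.null(cfg$gwas_scenario)) {
    n_shared <- ceiling(n_loci / 2)
    n_linked <- min(ceiling(n_loci / 4), n_loci - n_shared)
    cfg$gwas_scenario <- rep(c("shared_causal", "linked_causal", "null"),
                             c(n_shared, n_linked,
                               n_loci - n_shared - n_linked))
  }
  stopifnot(length(cfg$gwas_scenario) == n_loci,
            all(cfg$gwas_scenario %in%
                  c("shared_causal", "linked_causal", "null")))
  class(cfg) <- "sim_config"
  cfg
}

# ---- variant panel -------------------------------------------------------

# P(X < z1, Y < z2) under a standard bivariate normal with correlation rho
binorm_cdf <- function(z1, z2, rho) {
  if (rho > 0.99995) return(stats::pnorm(min(z1, z2)))
  if (abs(rho) < 1e-12) return(stats::pnorm(z1) * stats::pnorm(z2))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) stats::dnorm(x) * stats::pnorm((z2 - rho * x) / s),
                   -Inf, z1, rel.tol = 1e-9)$value
}

# correlation of the two threshold indicators given latent correlation rho
binary_corr <- function(rho, p1, p2) {
  z1 <- stats::qnorm(p1); z2 <- stats::qnorm(p2)
  p11 <- binorm_cdf(z1, z2, rho)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# latent AR(1) step correlation that realizes a target binary haplotype
# correlation for the pair of allele frequencies; capped at the maximum the
# margins allow
latent_rho_for <- function(p1, p2, target) {
  if (target <= 0) return(0)
  upper <- 0.9999
  if (binary_corr(upper, p1, p2) <= target) return(upper)
  stats::uniroot(function(r) binary_corr(r, p1, p2) - target,
                 c(0, upper), tol = 1e-6)$root
}

#' Build the variant panel implied by a simulation config
#'
#' One locus per chromosome; variants evenly spaced; per-locus MAF drawn
#' from `maf_range`; non-palindromic allele pairs. The latent AR(1) step
#' correlations that realize `ld_decay` on the haplotype scale are
#' pre-computed and attached.
#'
#' @param config a [sim_config()].
#' @return A [variant_table()] with extra columns `locus` and `latent_rho`.
#' @export
make_variant_panel <- function(config) {
  m <- config$variants_per_locus
  pairs <- list(c("A", "G"), c("T", "C"), c("C", "A"), c("G", "T"))
  rows <- lapply(seq_len(config$n_loci), function(l) {
    base_maf <- stats::runif(1, config$maf_range[1], config$maf_range[2])
    maf <- pmin(pmax(base_maf + stats::runif(m, -0.01, 0.01), 0.05), 0.5)
    al <- pairs[(seq_len(m) + l) %% length(pairs) + 1L]
    data.frame(id = sprintf("rsL%d_%02d", l, seq_len(m)),
               chrom = as.character(l),
               pos = 1000000L + (seq_len(m) - 1L) * config$variant_spacing_bp,
               a1 = vapply(al, `[`, "", 1), a2 = vapply(al, `[`, "", 2),
               eaf = maf, locus = l, stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  rho <- numeric(nrow(panel))
  for (j in seq_len(nrow(panel))) {
    if (j == 1 || panel$locus[j] != panel$locus[j - 1]) { rho[j] <- 0; next }
    rho[j] <- latent_rho_for(panel$eaf[j - 1], panel$eaf[j], config$ld_decay)
  }
  panel$latent_rho <- rho
  validate_variant_table(panel)
  class(panel) <- c("variant_table", "data.frame")
  panel
}

#' Gene annotation implied by a simulation config
#'
#' `genes_per_locus` genes per locus; the first (`gene_L<l>_1`) sits at the
#' locus centre and carries any planted effect, the rest are shifted by
#' 50 kb steps and stay null under the default planting.
#'
#' @param config a [sim_config()].
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `locus`.
#' @export
make_gene_annotation <- function(config) {
  span <- (config$variants_per_locus - 1L) * config$variant_spacing_bp
  centre <- 1000000L + span %/% 2L
  rows <- lapply(seq_len(config$n_loci), function(l) {
    k <- seq_len(config$genes_per_locus)
    data.frame(gene_id = sprintf("gene_L%d_%d", l, k),
               chrom = as.character(l),
               start = centre + (k - 1L) * 50000L - 5000L,
               end = centre + (k - 1L) * 50000L + 5000L,
               strand = "+", locus = l, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# resolve default planted effects and GWAS causal variants (realized-LD
# choices are made later, once genotypes exist)
plan_truth <- function(config, panel, annotation) {
  mid <- config$variants_per_locus %/% 2L + 1L
  planted <- config$planted_eqtls
  if (is.null(planted)) {
    active <- paste(intersect(config$eqtl_cell_types, config$cell_types),
                    collapse = ",")
    keep <- which(config$gwas_scenario != "null")
    planted <- data.frame(
      gene_id = sprintf("gene_L%d_1", keep),
      variant_id = panel$id[match(keep, panel$locus) + mid - 1L],
      cell_types = active,
      effect = config$eqtl_effect,
      stringsAsFactors = FALSE)
  }
  stopifnot(all(planted$gene_id %in% annotation$gene_id),
            all(planted$variant_id %in% panel$id))
  gwas <- data.frame(locus = seq_len(config$n_loci),
                     scenario = config$gwas_scenario,
                     expr_causal = NA_character_,
                     trait_causal = NA_character_,
                     realized_r2 = NA_real_,
                     z = ifelse(config$gwas_scenario == "null", 0,
                                config$gwas_z),
                     stringsAsFactors = FALSE)
  loc_of_variant <- panel$locus[match(planted$variant_id, panel$id)]
  gwas$expr_causal <- planted$variant_id[match(gwas$locus, loc_of_variant)]
  list(planted_eqtls = planted, gwas = gwas,
       interactions = config$interaction_effects,
       # gene baselines are a biological property shared by all datasets
       baselines = stats::runif(nrow(annotation),
                                config$baseline_log_mean[1],
                                config$baseline_log_mean[2]))
}

# is a planted effect active for (gene, cell type)? returns effect or 0
planted_effect <- function(truth, gene, cell_type) {
  pl <- truth$planted_eqtls
  hit <- pl$gene_id == gene &
    (pl$cell_types == "all" |
       vapply(strsplit(pl$cell_types, ","),
              function(x) cell_type %in% x, logical(1)))
  if (any(hit)) pl$effect[which(hit)[1]] else 0
}

# ---- generators ----------------------------------------------------------

#' Simulate LD-structured diploid genotypes
#'
#' Two haplotypes per subject are generated by thresholding an AR(1)
#' Gaussian process at MAF-matched quantiles and summed to a dosage. The
#' latent step correlations stored in the panel are calibrated so the
#' realized correlation between adjacent variants' haplotypes matches the
#' config's `ld_decay`.
#'
#' Uses the current RNG state; seed control belongs to the caller (or to
#' [simulate_cohort()]).
#'
#' @param config a [sim_config()].
#' @param panel a panel from [make_variant_panel()].
#' @param subjects subject identifiers (default `S1..Sn`).
#' @return A [genotype_matrix()] whose variant `eaf` is the realized
#'   dosage-based frequency.
#' @export
simulate_genotypes <- function(config, panel = NULL, subjects = NULL) {
  if (is.null(panel)) panel <- make_variant_panel(config)
  n <- config$n_subjects
  if (is.null(subjects)) subjects <- sprintf("S%d", seq_len(n))
  stopifnot(length(subjects) == n)
  m <- nrow(panel)
  hap <- function() {
    g <- matrix(0, n, m)
    g[, 1] <- stats::rnorm(n)
    for (j in 2:m) {
      r <- panel$latent_rho[j]
      g[, j] <- r * g[, j - 1] + sqrt(1 - r^2) * stats::rnorm(n)
    }
    sweep(g, 2, stats::qnorm(panel$eaf), "<") * 1L
  }
  dos <- hap() + hap()
  vt <- panel
  vt$eaf <- colMeans(dos) / 2
  genotype_matrix(dos, vt, subjects = subjects)
}

#' Simulate subject covariates and pathology scores
#'
#' Age, sex, RIN, PMI, library batch, an ordinal Lewy-body-style pathology
#' score (0--4, weighted toward low grades) and a diagnostic group.
#'
#' @param config a [sim_config()].
#' @param subjects subject identifiers.
#' @return data.frame, one row per subject.
#' @export
simulate_covariates <- function(config, subjects) {
  n <- length(subjects)
  score <- sample(0:4, n, replace = TRUE, prob = c(0.35, 0.2, 0.18, 0.15, 0.12))
  data.frame(subject_id = subjects,
             age = round(stats::rnorm(n, 77, 8)),
             sex = sample(0:1, n, replace = TRUE),
             rin = round(stats::rnorm(n, 7.5, 1), 1),
             pmi = round(pmax(stats::rnorm(n, 6, 2), 1), 1),
             batch = sprintf("b%d", sample(seq_len(config$n_batches), n,
                                           replace = TRUE)),
             pathology_score = score,
             group = ifelse(score > 0, "PD", "Ctrl"),
             stringsAsFactors = FALSE)
}

#' Simulate single-nucleus UMI counts with planted cis effects
#'
#' Per cell, gene counts are negative-binomial with log mean =
#' gene baseline + log(library factor) + batch shift + dosage x effect for
#' planted eQTLs active in the cell's type + dosage x pathology x effect for
#' planted dynamic eQTLs. Library factors are log-normal.
#'
#' @param config a [sim_config()].
#' @param genotypes a [genotype_matrix()] for the dataset's subjects.
#' @param covariates data.frame from [simulate_covariates()].
#' @param truth truth list from [plan_truth()]/[simulate_cohort()]; `NULL`
#'   plants nothing (all-null counts).
#' @param annotation gene annotation (defaults to the config's).
#' @param dataset label used in cell ids.
#' @return A [cell_counts()].
#' @export
simulate_cells <- function(config, genotypes, covariates, truth = NULL,
                           annotation = NULL, dataset = "D1") {
  if (is.null(annotation)) annotation <- make_gene_annotation(config)
  genes <- annotation$gene_id
  subjects <- genotypes$subjects
  n <- length(subjects); g <- length(genes)
  baseline <- truth$baselines %||%
    stats::runif(g, config$baseline_log_mean[1], config$baseline_log_mean[2])
  batches <- sort(unique(covariates$batch))
  bshift <- matrix(stats::rnorm(length(batches) * g, 0, config$batch_sd),
                   length(batches), g, dimnames = list(batches, NULL))
  sb <- covariates$batch[match(subjects, covariates$subject_id)]
  score <- covariates$pathology_score[match(subjects, covariates$subject_id)]
  ncell <- config$cells_per_subject_per_type

  blocks <- vector("list", length(config$cell_types))
  meta <- vector("list", length(config$cell_types))
  for (ti in seq_along(config$cell_types)) {
    ct <- config$cell_types[ti]
    logM <- matrix(baseline, n, g, byrow = TRUE) + bshift[sb, , drop = FALSE]
    if (!is.null(truth)) {
      pl <- truth$planted_eqtls
      for (k in seq_len(nrow(pl))) {
        eff <- planted_effect(list(planted_eqtls = pl[k, , drop = FALSE]),
                              pl$gene_id[k], ct)
        if (eff != 0) {
          jg <- match(pl$gene_id[k], genes)
          logM[, jg] <- logM[, jg] +
            eff * genotypes$dosage[, pl$variant_id[k]]
        }
      }
      ia <- truth$interactions
      if (!is.null(ia)) for (k in seq_len(nrow(ia))) {
        if (ia$cell_type[k] == ct) {
          jg <- match(ia$gene_id[k], genes)
          logM[, jg] <- logM[, jg] +
            ia$effect[k] * genotypes$dosage[, ia$variant_id[k]] * score
        }
      }
    }
    idx <- rep(seq_len(n), each = ncell)
    lib <- stats::rlnorm(n * ncell, 0, config$libsize_sdlog)
    mu <- exp(logM[idx, , drop = FALSE]) * lib
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = config$nb_dispersion),
                  nrow(mu), g)
    blocks[[ti]] <- cnt
    meta[[ti]] <- data.frame(
      cell_id = sprintf("%s_%s_%s_c%d", dataset, ct, subjects[idx],
                        rep(seq_len(ncell), n)),
      subject_id = subjects[idx], cell_type = ct, batch = sb[idx],
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, blocks)
  cm <- do.call(rbind, meta)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  rownames(counts) <- cm$cell_id
  colnames(counts) <- genes
  cell_counts(counts, cm, genes)
}

#' Simulate GWAS summary statistics under shared/linked/null scenarios
#'
#' Works in z-space: with `R` the realized dosage-correlation matrix of a
#' locus and `z*` the causal-variant z-scores, marginal z-scores are drawn
#' from `N(R z*, R)`; `beta = z / sqrt(2 f (1-f) n)` and `se = beta / z`
#' put them on a per-allele scale for a unit-variance trait. The trait
#' causal variant equals the expression causal variant under
#' `shared_causal`, and is the variant whose realized r2 to it is closest
#' to `linked_r2_target` under `linked_causal`; the choices are written
#' back into `truth$gwas`.
#'
#' @param config a [sim_config()].
#' @param genotypes LD-reference [genotype_matrix()] (pooled subjects).
#' @param truth truth list; updated scenario bookkeeping is attached as
#'   attribute `"truth_gwas"` of the result.
#' @return A [sumstats()] table with `chr`/`bp` columns.
#' @export
simulate_gwas <- function(config, genotypes, truth) {
  panel <- genotypes$variants
  out <- vector("list", config$n_loci)
  gw <- truth$gwas
  for (l in seq_len(config$n_loci)) {
    jj <- which(panel$locus == l)
    ids <- panel$id[jj]
    R <- stats::cor(genotypes$dosage[, jj, drop = FALSE])
    zstar <- numeric(length(jj))
    sc <- gw$scenario[l]
    if (sc != "null" && !is.na(gw$expr_causal[l])) {
      ec <- match(gw$expr_causal[l], ids)
      if (sc == "shared_causal") {
        tc <- ec
      } else {
        r2 <- R[ec, ]^2
        cand <- setdiff(seq_along(ids), ec)
        tc <- cand[which.min(abs(r2[cand] - config$linked_r2_target))]
        gw$realized_r2[l] <- r2[tc]
      }
      zstar[tc] <- gw$z[l]
      gw$trait_causal[l] <- ids[tc]
    }
    z <- drop(R %*% zstar) + drop(rmvnorm_chol(1, R))
    f <- pmin(pmax(panel$eaf[jj], 1e-3), 1 - 1e-3)
    se <- 1 / sqrt(2 * f * (1 - f) * config$gwas_n)
    out[[l]] <- data.frame(snp = ids, chr = panel$chrom[jj],
                           bp = panel$pos[jj], a1 = panel$a1[jj],
                           a2 = panel$a2[jj], freq = f,
                           beta = z * se, se = se,
                           p = 2 * stats::pnorm(-abs(z)),
                           n = config$gwas_n, stringsAsFactors = FALSE)
  }
  ss <- sumstats(do.call(rbind, out), trait = "trait_gwas")
  attr(ss, "truth_gwas") <- gw
  ss
}

#' Simulate phased allele-specific UMI counts
#'
#' For subjects heterozygous at a tested variant, per cell type, the `a1`
#' UMI count is beta-binomial with mean `plogis(kappa * effect)` (0.5 for
#' variants without a planted effect in that cell type) and overdispersion
#' `ase_overdispersion`. Homozygous subjects emit no rows. Tested pairs are
#' the planted eQTLs plus, for every other gene, its locus mid variant
#' (null imbalance).
#'
#' @param config a [sim_config()].
#' @param genotypes [genotype_matrix()] of the ASE cohort.
#' @param truth truth list.
#' @param annotation gene annotation (defaults to the config's).
#' @return data.frame of phased allele counts (see [read_allele_counts()]).
#' @export
simulate_ase <- function(config, genotypes, truth, annotation = NULL) {
  if (is.null(annotation)) annotation <- make_gene_annotation(config)
  mid <- config$variants_per_locus %/% 2L + 1L
  panel <- genotypes$variants
  pl <- truth$planted_eqtls
  extra <- annotation[!annotation$gene_id %in% pl$gene_id, , drop = FALSE]
  pairs <- rbind(
    data.frame(gene_id = pl$gene_id, variant_id = pl$variant_id,
               stringsAsFactors = FALSE),
    data.frame(gene_id = extra$gene_id,
               variant_id = panel$id[match(extra$locus, panel$locus) + mid - 1L],
               stringsAsFactors = FALSE))
  out <- vector("list", nrow(pairs) * length(config$cell_types))
  k <- 0L
  for (i in seq_len(nrow(pairs))) {
    dos <- genotypes$dosage[, pairs$variant_id[i]]
    het <- which(!is.na(dos) & abs(dos - 1) < 1e-9)
    if (!length(het)) next
    for (ct in config$cell_types) {
      eff <- planted_effect(truth, pairs$gene_id[i], ct)
      mu <- stats::plogis(config$ase_kappa * eff)
      tot <- stats::rpois(length(het), config$ase_mean_umis)
      keep <- tot > 0
      if (!any(keep)) next
      a1 <- rbetabinom(sum(keep), tot[keep], mu, config$ase_overdispersion)
      k <- k + 1L
      out[[k]] <- data.frame(subject_id = genotypes$subjects[het][keep],
                             cell_type = ct,
                             variant_id = pairs$variant_id[i],
                             gene_id = pairs$gene_id[i],
                             a1_umis = a1, total_umis = tot[keep],
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(data.frame(subject_id = character(), cell_type = character(),
                                 variant_id = character(), gene_id = character(),
                                 a1_umis = integer(), total_umis = integer()))
  do.call(rbind, out[seq_len(k)])
}

#' Simulate a complete multi-dataset cohort with ground truth
#'
#' Runs every generator under the config's seed: a shared variant panel and
#' gene annotation, per-dataset genotypes/covariates/single-nucleus counts,
#' pooled-LD GWAS summary statistics, and phased allele counts for the
#' first dataset's subjects. Fixed seed gives byte-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `panel`, `annotation`, `truth`, `datasets`
#'   (each: `genotypes`, `covariates`, `cells`), `gwas`, `ase`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  panel <- make_variant_panel(config)
  annotation <- make_gene_annotation(config)
  truth <- plan_truth(config, panel, annotation)
  datasets <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    subjects <- sprintf("D%d_S%d", d, seq_len(config$n_subjects))
    gt <- simulate_genotypes(config, panel, subjects)
    cov <- simulate_covariates(config, subjects)
    cells <- simulate_cells(config, gt, cov, truth, annotation,
                            dataset = sprintf("D%d", d))
    datasets[[d]] <- list(genotypes = gt, covariates = cov, cells = cells)
  }
  pooled <- genotype_matrix(
    do.call(rbind, lapply(datasets, function(d) d$genotypes$dosage)),
    {
      vt <- panel
      vt$eaf <- colMeans(do.call(rbind, lapply(datasets, function(d)
        d$genotypes$dosage))) / 2
      vt
    },
    subjects = unlist(lapply(datasets, function(d) d$genotypes$subjects)))
  gwas <- simulate_gwas(config, pooled, truth)
  truth$gwas <- attr(gwas, "truth_gwas")
  ase <- simulate_ase(config, datasets[[1]]$genotypes, truth, annotation)
  list(config = config, panel = panel, annotation = annotation,
       truth = truth, datasets = datasets, pooled_genotypes = pooled,
       gwas = gwas, ase = ase)
}
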