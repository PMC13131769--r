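# beta-binomial log density in the (mu, phi) correlation parameterization;
# phi -> 0 recovers the binomial. Below phi = 1e-6 the lbeta formulation
# loses precision (a, b ~ 1/phi), so the binomial limit takes over there.
dbetabinom_log <- function(x, n, mu, phi) {
  if (phi < 1e-6) return(stats::dbinom(x, n, mu, log = TRUE))
  a <- mu * (1 - phi) / phi
  b <- (1 - mu) * (1 - phi) / phi
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

bb_negll <- function(par, x, n, mu_fixed = NULL) {
  if (is.null(mu_fixed)) {
    mu <- stats::plogis(par[1]); phi <- stats::plogis(par[2])
  } else {
    mu <- mu_fixed; phi <- stats::plogis(par[1])
  }
  mu <- min(max(mu, 1e-9), 1 - 1e-9)
  phi <- min(phi, 1 - 1e-9)
  -sum(dbetabinom_log(x, n, mu, phi))
}

# ML fit of the beta-binomial with logit-link mean and overdispersion phi in
# [0, 1); multiple starts guard the boundary-prone likelihood
bb_fit <- function(x, n, mu_fixed = NULL, mu_starts = c(0.3, 0.5, 0.7),
                   phi_starts = c(0.01, 0.1)) {
  binom_ll <- function(mu) sum(stats::dbinom(x, n, mu, log = TRUE))
  if (!is.null(mu_fixed)) {
    opt <- stats::optimize(function(lp) bb_negll(lp, x, n, mu_fixed),
                           c(-30, 10), tol = 1e-10)
    out <- list(mu = mu_fixed, phi = stats::plogis(opt$minimum),
                ll = -opt$objective)
    # the phi -> 0 binomial limit is a boundary candidate the golden-section
    # search can stop short of
    if (binom_ll(mu_fixed) >= out$ll) {
      out$phi <- 0
      out$ll <- binom_ll(mu_fixed)
    }
    return(out)
  }
  best <- NULL
  for (ph in phi_starts) {
    for (mu in mu_starts) {
      o <- stats::optim(c(stats::qlogis(mu), stats::qlogis(ph)), bb_negll,
                        x = x, n = n, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
      # restart from the optimum; Nelder-Mead benefits from a fresh simplex
      o <- stats::optim(o$par, bb_negll, x = x, n = n,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  out <- list(mu = stats::plogis(best$par[1]),
              phi = stats::plogis(best$par[2]), ll = -best$value)
  mu_b <- min(max(sum(x) / sum(n), 1e-9), 1 - 1e-9)
  if (binom_ll(mu_b) >= out$ll) {
    out <- list(mu = mu_b, phi = 0, ll = binom_ll(mu_b))
  }
  out
}

#' Pseudobulk and filter phased allele counts
#'
#' Sums phased UMI counts to (subject, cell type, variant, gene) rows and
#' drops variants whose summed total across retained subjects (per cell
#' type) is below `min_umis` (default 20; the boundary is inclusive).
#' Homozygous subjects contribute no rows upstream.
#'
#' @param raw phased allele counts (see [read_allele_counts()]).
#' @param min_umis minimum summed phased UMIs per variant and cell type.
#' @return aggregated, filtered data.frame in the same column layout.
#' @export
pseudobulk_ase <- function(raw, min_umis = 20) {
  key <- paste(raw$subject_id, raw$cell_type, raw$variant_id, raw$gene_id,
               sep = "\r")
  sums <- rowsum(cbind(a1 = raw$a1_umis, tot = raw$total_umis), key)
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  agg <- data.frame(subject_id = parts[, 1], cell_type = parts[, 2],
                    variant_id = parts[, 3], gene_id = parts[, 4],
                    a1_umis = sums[, "a1"], total_umis = sums[, "tot"],
                    stringsAsFactors = FALSE, row.names = NULL)
  vkey <- paste(agg$cell_type, agg$variant_id, agg$gene_id, sep = "\r")
  grand <- rowsum(agg$total_umis, vkey)
  agg <- agg[grand[vkey, 1] >= min_umis, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Beta-binomial allelic-imbalance test for one variant/gene/cell type
#'
#' ML fit of `a1_i ~ BetaBinomial(total_i, mu, phi)` across subjects with a
#' logit-link mean and free overdispersion, against the null with `mu`
#' fixed at 0.5 (`phi` still free): a likelihood-ratio test on chisq(1).
#' Fully boundary-imbalanced input yields a clipped `mu_hat` with
#' `boundary = TRUE`.
#'
#' @param a1 per-subject `a1` UMI counts.
#' @param total per-subject total phased UMI counts.
#' @param alpha significance cutoff for the returned flag (default 0.05).
#' @return list `mu_hat`, `phi_hat`, `log_odds`, `lrt`, `p`, `significant`,
#'   `n_subjects`, `total_umis`, `boundary`.
#' @export
betabin_test <- function(a1, total, alpha = 0.05) {
  keep <- total > 0
  a1 <- a1[keep]; total <- total[keep]
  if (length(a1) < 3) stop("betabin_test needs >= 3 subjects with reads")
  stopifnot(all(a1 >= 0), all(a1 <= total))
  boundary <- all(a1 == 0) || all(a1 == total)
  alt <- bb_fit(a1, total)
  null <- bb_fit(a1, total, mu_fixed = 0.5)
  mu <- min(max(alt$mu, 1e-6), 1 - 1e-6)
  lrt <- max(0, 2 * (alt$ll - null$ll))
  p <- stats::pchisq(lrt, 1, lower.tail = FALSE)
  list(mu_hat = mu, phi_hat = alt$phi,
       log_odds = stats::qlogis(mu), lrt = lrt, p = p,
       significant = p <= alpha, n_subjects = length(a1),
       total_umis = sum(total), boundary = boundary)
}

#' Run the allelic-imbalance test over a filtered ASE table
#'
#' @param ase filtered table from [pseudobulk_ase()].
#' @param min_subjects minimum informative subjects per test (default 3).
#' @param alpha significance cutoff (default 0.05).
#' @return data.frame: `gene_id`, `variant_id`, `cell_type`, `n_subjects`,
#'   `total_umis`, `mu_hat`, `phi_hat`, `log_odds`, `p`, `significant`.
#' @export
ase_test_all <- function(ase, min_subjects = 3, alpha = 0.05) {
  key <- paste(ase$gene_id, ase$variant_id, ase$cell_type, sep = "\r")
  idx <- split(seq_len(nrow(ase)), key)
  rows <- lapply(idx, function(ii) {
    if (sum(ase$total_umis[ii] > 0) < min_subjects) return(NULL)
    ft <- betabin_test(ase$a1_umis[ii], ase$total_umis[ii], alpha = alpha)
    data.frame(gene_id = ase$gene_id[ii[1]], variant_id = ase$variant_id[ii[1]],
               cell_type = ase$cell_type[ii[1]], n_subjects = ft$n_subjects,
               total_umis = ft$total_umis, mu_hat = ft$mu_hat,
               phi_hat = ft$phi_hat, log_odds = ft$log_odds, p = ft$p,
               significant = ft$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_id = character(), variant_id = character(),
                      cell_type = character(), n_subjects = integer(),
                      total_umis = integer(), mu_hat = numeric(),
                      phi_hat = numeric(), log_odds = numeric(),
                      p = numeric(), significant = logical()))
  rownames(out) <- NULL
  out
}

#' ASE-eQTL effect-size concordance
#'
#' Pairs allelic log-odds with eQTL meta effects on (gene, variant, cell
#' type) — both on the `a1` allele — and reports the Pearson correlation
#' with its two-sided t-based p, plus the paired table for plotting.
#'
#' @param ase results from [ase_test_all()].
#' @param eqtl meta records with `beta_re` (or eQTL records with `beta`).
#' @return list `r`, `p`, `n`, `pairs`.
#' @export
ase_concordance <- function(ase, eqtl) {
  bcol <- if ("beta_re" %in% names(eqtl)) "beta_re" else "beta"
  m <- merge(ase[, c("gene_id", "variant_id", "cell_type", "log_odds")],
             eqtl[, c("gene_id", "variant_id", "cell_type", bcol)],
             by = c("gene_id", "variant_id", "cell_type"))
  names(m)[names(m) == bcol] <- "eqtl_beta"
  if (nrow(m) < 3) return(list(r = NA_real_, p = NA_real_, n = nrow(m),
                               pairs = m))
  ct <- stats::cor.test(m$log_odds, m$eqtl_beta, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m), pairs = m)
}
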