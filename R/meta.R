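#' Fixed-effects inverse-variance meta-analysis
#'
#' Weights `w_i = 1/se_i^2`; pooled `beta = sum(w b)/sum(w)`;
#' `se = 1/sqrt(sum(w))`; two-sided normal p; Cochran's
#' `Q = sum(w (b - beta)^2)`.
#'
#' @param beta study effect sizes.
#' @param se study standard errors (> 0).
#' @return list `beta`, `se`, `p`, `Q`, `k`.
#' @export
meta_fixed <- function(beta, se) {
  if (!length(beta)) stop("meta_fixed needs at least one study")
  stopifnot(length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  list(beta = b, se = s, p = 2 * stats::pnorm(-abs(b / s)),
       Q = sum(w * (beta - b)^2), k = length(beta))
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with the
#' fixed-effects weights, then inverse-variance pooling with
#' `w*_i = 1/(se_i^2 + tau2)`. Reduces to [meta_fixed()] when `Q <= k-1`.
#'
#' @inheritParams meta_fixed
#' @return list `beta`, `se`, `p`, `tau2`, `Q`, `k`.
#' @export
meta_random <- function(beta, se) {
  k <- length(beta)
  if (k < 2) stop("meta_random needs k >= 2 studies")
  stopifnot(length(se) == k, all(se > 0))
  w <- 1 / se^2
  fe <- meta_fixed(beta, se)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (fe$Q - (k - 1)) / C)
  ws <- 1 / (se^2 + tau2)
  b <- sum(ws * beta) / sum(ws)
  s <- 1 / sqrt(sum(ws))
  list(beta = b, se = s, p = 2 * stats::pnorm(-abs(b / s)),
       tau2 = tau2, Q = fe$Q, k = k)
}

# profile log-likelihood of the normal marginal model b_i ~ N(beta, se_i^2 +
# tau2), maximized over beta in closed form
re2_profile_ll <- function(tau2, beta, se) {
  v <- se^2 + tau2
  w <- 1 / v
  bhat <- sum(w * beta) / sum(w)
  -0.5 * sum(log(2 * pi * v) + (beta - bhat)^2 / v)
}

#' Han-Eskin RE2 random-effects likelihood-ratio test
#'
#' Tests `beta = 0, tau2 = 0` against the normal marginal likelihood
#' `b_i ~ N(beta, se_i^2 + tau2)` maximized over both parameters (`tau2`
#' profiled by bounded one-dimensional search over
#' `[0, 100 * max(se^2)]`). The null of the LR statistic `S` is the
#' half-half mixture `p = 0.5 P(chisq_1 >= S) + 0.5 P(chisq_2 >= S)`,
#' which detects associations with between-study heterogeneity.
#'
#' @inheritParams meta_fixed
#' @return list `p`, `S`, `tau2`, `converged` (`FALSE` means the optimizer
#'   failed and the fixed-effects p was substituted).
#' @export
meta_re2 <- function(beta, se) {
  k <- length(beta)
  if (k < 2) stop("meta_re2 needs k >= 2 studies")
  stopifnot(length(se) == k, all(se > 0))
  ll0 <- -0.5 * sum(log(2 * pi * se^2) + beta^2 / se^2)
  fit <- tryCatch({
    upper <- 100 * max(se^2)
    opt <- stats::optimize(re2_profile_ll, c(0, upper), beta = beta, se = se,
                           maximum = TRUE, tol = 1e-10)
    ll_edge <- re2_profile_ll(0, beta, se)
    if (ll_edge >= opt$objective) list(tau2 = 0, ll = ll_edge)
    else list(tau2 = opt$maximum, ll = opt$objective)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    fe <- meta_fixed(beta, se)
    return(list(p = fe$p, S = NA_real_, tau2 = NA_real_, converged = FALSE))
  }
  S <- max(0, 2 * (fit$ll - ll0))
  p <- 0.5 * stats::pchisq(S, 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(S, 2, lower.tail = FALSE)
  list(p = p, S = S, tau2 = fit$tau2, converged = TRUE)
}

#' Meta-analyze per-dataset eQTL records
#'
#' Joins per-dataset eQTL tables on (gene, variant, cell type) and computes
#' fixed-effects, DerSimonian-Laird random-effects and RE2 statistics per
#' triple. Per the downstream convention, significance testing uses the RE2
#' p while effect sizes and standard errors are taken from the RE model.
#' Triples present in fewer than `min_k` datasets are dropped; with a
#' single study FE = RE and the RE2 p falls back to the FE p.
#'
#' @param eqtl_list list of eQTL data.frames from [map_cis()] (one per
#'   dataset).
#' @param min_k minimum number of contributing datasets (default 2).
#' @return data.frame of meta records: `gene_id`, `variant_id`, `cell_type`,
#'   `k`, `beta_fe`, `se_fe`, `p_fe`, `Q`, `beta_re`, `se_re`, `p_re`,
#'   `tau2`, `p_re2`.
#' @export
meta_analyze <- function(eqtl_list, min_k = 2) {
  all <- do.call(rbind, eqtl_list)
  if (is.null(all) || !nrow(all))
    return(data.frame(gene_id = character(), variant_id = character(),
                      cell_type = character(), k = integer(),
                      beta_fe = numeric(), se_fe = numeric(), p_fe = numeric(),
                      Q = numeric(), beta_re = numeric(), se_re = numeric(),
                      p_re = numeric(), tau2 = numeric(), p_re2 = numeric()))
  key <- paste(all$gene_id, all$variant_id, all$cell_type, sep = "\r")
  idx <- split(seq_len(nrow(all)), key)
  rows <- lapply(idx, function(ii) {
    k <- length(ii)
    if (k < min_k) return(NULL)
    b <- all$beta[ii]; s <- all$se[ii]
    fe <- meta_fixed(b, s)
    if (k >= 2) {
      re <- meta_random(b, s)
      r2 <- meta_re2(b, s)
      p_re2 <- r2$p; tau2 <- re$tau2
      beta_re <- re$beta; se_re <- re$se; p_re <- re$p
    } else {
      p_re2 <- fe$p; tau2 <- 0
      beta_re <- fe$beta; se_re <- fe$se; p_re <- fe$p
    }
    data.frame(gene_id = all$gene_id[ii[1]], variant_id = all$variant_id[ii[1]],
               cell_type = all$cell_type[ii[1]], k = k,
               beta_fe = fe$beta, se_fe = fe$se, p_fe = fe$p, Q = fe$Q,
               beta_re = beta_re, se_re = se_re, p_re = p_re,
               tau2 = tau2, p_re2 = p_re2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
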