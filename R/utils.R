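# internal numerics shared across modules

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# draw one sample from N(0, Sigma) given an LD correlation matrix; a small
# ridge is added automatically when the Cholesky fails on near-singular input
rmvnorm_chol <- function(n, sigma, ridge = 1e-8) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  tries <- 0
  while (is.null(ch) && tries < 8) {
    sigma <- sigma + diag(ridge, nrow(sigma))
    ridge <- ridge * 10
    tries <- tries + 1
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
  }
  if (is.null(ch)) stop("covariance matrix could not be factorized")
  matrix(stats::rnorm(n * nrow(sigma)), n) %*% ch
}

# beta-binomial sampler in the (mu, phi) correlation parameterization used by
# the ASE module: phi = 0 reduces to the binomial
rbetabinom <- function(n, size, mu, phi) {
  mu <- rep_len(mu, n); phi <- rep_len(phi, n); size <- rep_len(size, n)
  out <- integer(n)
  bb <- phi > 1e-12
  if (any(bb)) {
    a <- mu[bb] * (1 - phi[bb]) / phi[bb]
    b <- (1 - mu[bb]) * (1 - phi[bb]) / phi[bb]
    pr <- stats::rbeta(sum(bb), a, b)
    out[bb] <- stats::rbinom(sum(bb), size[bb], pr)
  }
  if (any(!bb)) out[!bb] <- stats::rbinom(sum(!bb), size[!bb], mu[!bb])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
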