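# independent brute-force oracles, kept free of the code paths they check

# Mann-Whitney U of group a (values, no ties assumed for the exact case)
oracle_u <- function(a, b) sum(outer(a, b, `>`))

# exact two-sided rank-sum p by full enumeration of the C(n, na) equally
# likely assignments of the pooled values to group a
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  splits <- combn(n, length(a), simplify = FALSE)
  us <- vapply(splits, function(idx)
    oracle_u(pooled[idx], pooled[-idx]), numeric(1))
  mid <- length(a) * length(b) / 2
  u_obs <- oracle_u(a, b)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

# two-sided Fisher p by enumeration of all tables with the observed
# margins, probability-mass definition
oracle_fisher_p <- function(t) {
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); n <- sum(t)
  amin <- max(0, r1 + c1 - n); amax <- min(r1, c1)
  pr <- vapply(amin:amax, function(a)
    dhyper(a, c1, n - c1, r1), numeric(1))
  obs <- dhyper(t[1, 1], c1, n - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# PCA by direct eigendecomposition of the covariance of the scaled data
oracle_pca <- function(m, center = TRUE, scale = TRUE) {
  x <- scale(t(m), center = center, scale = scale)
  es <- eigen(cov(x), symmetric = TRUE)
  list(values = es$values, vectors = es$vectors, scores = x %*% es$vectors)
}
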