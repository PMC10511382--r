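# Independent oracles used across test files. These deliberately avoid the
# package's own probability formulas: the score distribution is built by
# brute-force enumeration over encoding subsets, and rank-test p-values by
# full permutation enumeration.

# P(score = s) for a display of n letters each independently encoded with
# probability p, capped at capacity k: enumerate all 2^n encoding patterns.
oracle_score_pmf_fixed_k <- function(p, k, n = 6) {
  pmf <- numeric(n + 1)
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[1:n]
    prob <- prod(ifelse(bits == 1, p, 1 - p))
    s <- min(sum(bits), k)
    pmf[s + 1] <- pmf[s + 1] + prob
  }
  pmf
}

# mixture over the two-point capacity distribution (K = k0 + frac)
oracle_score_pmf <- function(p, K, n = 6) {
  k0 <- floor(K + 1e-12)
  frac <- K - k0
  pmf <- (1 - frac) * oracle_score_pmf_fixed_k(p, k0, n)
  if (frac > 0) pmf <- pmf + frac * oracle_score_pmf_fixed_k(p, k0 + 1, n)
  pmf
}

oracle_expected_score <- function(p, K, n = 6) {
  sum((0:n) * oracle_score_pmf(p, K, n))
}

# exact rank-sum p-value by enumerating every assignment of the pooled values
# to the x group (feasible for n_x + n_y <= 10)
oracle_wilcoxon_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  nx <- length(x)
  rk <- rank(pooled)
  W_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(length(pooled), nx)
  Ws <- apply(splits, 2, function(idx) sum(rk[idx]) - nx * (nx + 1) / 2)
  switch(alternative,
    less = mean(Ws <= W_obs),
    greater = mean(Ws >= W_obs),
    two.sided = min(1, 2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs)))
  )
}

# step-up BH adjustment written out longhand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
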