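# Independent brute-force oracles used to freeze expected values.

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
# (feasible for small N): fraction of draws overlapping the K marked items
# in at least k elements.
hypergeom_oracle_enum <- function(k, n, K, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Hypergeometric upper tail by term summation with lchoose (feasible for
# any moderate N); independent of the dhyper code path.
hypergeom_oracle_sum <- function(k, n, K, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  i <- i[n - i <= N - K]
  if (length(i) == 0) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# C(n1+n2, n1) assignments of the pooled values to group 1 (tie-free or
# tied inputs alike): two-sided p = 2*min(P(U <= u), P(U >= u)), capped.
mw_oracle_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  assignments <- utils::combn(n1 + n2, n1)
  U_all <- apply(assignments, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p_le <- mean(U_all <= U_obs)
  p_ge <- mean(U_all >= U_obs)
  min(1, 2 * min(p_le, p_ge))
}

# One-sided (group A greater) version of the same enumeration.
mw_oracle_enum_greater <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  assignments <- utils::combn(n1 + n2, n1)
  U_all <- apply(assignments, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mean(U_all >= U_obs)
}

# Adjusted Rand index between two labelings (closed form on the pair
# contingency table).
ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
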