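# Brute-force enumeration oracles for the exact tests. These deliberately
# recompute null distributions by direct enumeration, independently of the
# dynamic-programming implementations they check.

brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  p_le <- mean(ws <= w + 1e-9)
  p_ge <- mean(ws >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

brute_rank_sum_p <- function(x, y, alternative = "two.sided") {
  r <- rank(c(x, y))
  nx <- length(x)
  w <- sum(r[seq_len(nx)])
  idx <- utils::combn(length(r), nx)
  ws <- colSums(matrix(r[idx], nrow = nx))
  p_le <- mean(ws <= w + 1e-9)
  p_ge <- mean(ws >= w - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# Fisher's exact two-sided p for a 2x2 table by full hypergeometric
# enumeration (sum of point probabilities not exceeding the observed one).
brute_fisher_p <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided binomial p against p0 by direct summation of point
# probabilities not exceeding the observed one.
brute_binom_p <- function(k, n, p0 = 0.5) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}
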