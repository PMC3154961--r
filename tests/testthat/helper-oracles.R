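# Independent brute-force oracles for the exact tests. These are written from
# first principles (combinatorics and enumeration) and deliberately share no
# code with the implementation paths they check.

# Two-sided Fisher exact p for a 2x2 table by enumerating all tables with the
# observed margins: sum the probabilities of tables no more likely than the
# observed one (with the customary relative tolerance for ties).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  obs <- prob[ks == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Two-sided exact binomial p (minimum-likelihood convention): sum of all
# outcome probabilities not exceeding that of the observed outcome.
oracle_binom_p <- function(x, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# Upper-tail hypergeometric P(X >= k) by direct summation of the pmf.
oracle_hyper_upper <- function(N, K, n, k) {
  js <- k:min(n, K)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js) / choose(N, n))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n+m, n) group assignments of the pooled ranks (tie-free data).
oracle_wilcox_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(ix) sum(r[ix])) - nx * (nx + 1) / 2
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Naive CCGG counter used against the reference generator's registry.
oracle_ccgg_count <- function(seq) {
  n <- nchar(seq)
  if (n < 4) return(0L)
  hits <- 0L
  for (i in 1:(n - 3)) if (substr(seq, i, i + 3) == "CCGG") hits <- hits + 1L
  hits
}
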