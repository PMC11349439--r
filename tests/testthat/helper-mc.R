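# Monte-Carlo oracles, independent of the implementation under test:
# everything here is brute-force simulation of uniform random variables.

# Pr(wo*U1 + wr*U2 <= ew) with binomial standard error
mcWeightedSumProb <- function(ew, wo = 1, wr = 1, n = 1e5, seed = 1) {
  set.seed(seed)
  hit <- mean(wo * runif(n) + wr * runif(n) <= ew)
  list(prob = hit, se = sqrt(hit * (1 - hit) / n))
}

# Pr(U1 + ... + Uk <= x)
mcUniformSumProb <- function(x, k, n = 1e6, seed = 1) {
  set.seed(seed)
  s <- rowSums(matrix(runif(n * k), ncol = k))
  hit <- mean(s <= x)
  list(prob = hit, se = sqrt(hit * (1 - hit) / n))
}

expect_within3SE <- function(value, mc) {
  expect_lt(abs(value - mc$prob), 3 * max(mc$se, 1e-12))
}
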