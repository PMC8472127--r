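# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: hand formulas, brute-force
# enumeration and numerical quadrature.

# Kruskal-Wallis H by the textbook rank formula (no tie correction needed
# for untied data).
kwHOracle <- function(groups) {
  pooled <- unlist(groups)
  rk <- rank(pooled)
  N <- length(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rj <- tapply(rk, idx, sum)
  nj <- lengths(groups)
  12 / (N * (N + 1)) * sum(rj^2 / nj) - 3 * (N + 1)
}

# Exact permutation distribution of the Kruskal-Wallis H over all
# assignments of the pooled values to groups of the given sizes.
kwPermutationOracle <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  sizes <- lengths(groups)
  splitsA <- utils::combn(N, sizes[1])
  hs <- numeric(0)
  for (i in seq_len(ncol(splitsA))) {
    a <- splitsA[, i]
    rest <- setdiff(seq_len(N), a)
    splitsB <- utils::combn(rest, sizes[2])
    for (j in seq_len(ncol(splitsB))) {
      b <- splitsB[, j]
      cgrp <- setdiff(rest, b)
      hs <- c(hs, kwHOracle(list(pooled[a], pooled[b], pooled[cgrp])))
    }
  }
  hs
}

# Exact min-U Mann-Whitney distribution by enumeration of all splits.
mwPermutationOracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); m <- length(b); N <- n + m
  rk <- rank(pooled)
  splits <- utils::combn(N, n)
  apply(splits, 2, function(ix) {
    ua <- sum(rk[ix]) - n * (n + 1) / 2
    min(ua, n * m - ua)
  })
}

# Numerically integrated pixel-aperture ESF oracle: mean of the
# sigma-blurred unit step over a w1 x w2 box at center distance d, by
# 2D midpoint quadrature (independent of the generator's closed form).
esfQuadOracle <- function(d, sigma, w1, w2, nq = 61) {
  u1 <- (seq_len(nq) - 0.5) / nq * w1 - w1 / 2
  u2 <- (seq_len(nq) - 0.5) / nq * w2 - w2 / 2
  vapply(d, function(di) {
    mean(outer(u1, u2, function(p, q2) pnorm((di + p + q2) / sigma)))
  }, numeric(1))
}

# Quick small flat-field set for NNPS tests.
makeFlatSet <- function(n = 4, mean = 1000, sd = 10, pitch = 0.1,
                        side = 520, seedBase = 100) {
  lapply(seq_len(n), function(i)
    makeFlatField(mean, sd, pitch, c(side, side), seed = seedBase + i)$image)
}
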