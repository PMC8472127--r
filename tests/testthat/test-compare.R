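test_that("binCurve selects range-inclusive grid points", {
  f <- seq(0, 3, by = 0.1)
  cv <- FrequencySeries(f, exp(-f), plane = "object", quantity = "eDQE")
  expect_length(binCurve(cv, c(0, 1)), 11)
  expect_length(binCurve(cv, c(0, 1.25)), 13)
  expect_length(binCurve(cv, c(1.15, 2.15)), 10)
  expect_error(binCurve(cv, c(5, 6)), "no grid points")
})

test_that("Kruskal-Wallis matches the brute-force rank formula and enumeration", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  kw <- kruskalWallis(groups)
  expect_equal(kw$df, 2)
  expect_equal(kw$H, kwHOracle(groups), tolerance = 1e-12)

  hs <- kwPermutationOracle(groups)
  expect_length(hs, 90)  # 6! / (2! 2! 2!)
  pExact <- mean(hs >= kw$H - 1e-9)
  expect_equal(pExact, 6 / 90, tolerance = 1e-12)
  # the chi-square approximation is close to exact even at these sizes
  expect_lt(abs(kw$p - pExact), 0.06)

  g2 <- list(c(2, 9, 4), c(7, 1, 3), c(8, 6, 5))
  kw2 <- kruskalWallis(g2)
  expect_equal(kw2$H, kwHOracle(g2), tolerance = 1e-12)

  ties <- list(c(1, 1, 1), c(1, 1), c(1, 1, 1))
  kwT <- kruskalWallis(ties)
  expect_equal(kwT$H, 0)
  expect_equal(kwT$p, 1)
  expect_error(kruskalWallis(list(1:3, numeric(0))), "empty")
})

test_that("Kruskal-Wallis agrees with stats::kruskal.test under ties", {
  g <- list(c(1, 2, 2, 5), c(2, 3, 8), c(4, 4, 9, 10))
  kw <- kruskalWallis(g)
  kt <- stats::kruskal.test(unlist(g),
                            factor(rep(1:3, lengths(g))))
  expect_equal(kw$H, unname(kt$statistic))
  expect_equal(kw$p, kt$p.value)
})

test_that("Mann-Whitney U follows the min convention with tie-corrected Z", {
  sep <- mannWhitney(1:11, 12:22)          # complete separation, n = m = 11
  expect_equal(sep$U, 0)
  expect_equal(sep$Z, -60.5 / sqrt(11 * 11 * 23 / 12), tolerance = 1e-12)
  expect_equal(round(sep$Z, 2), -3.97)

  same <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 4.5)
  expect_equal(same$Z, 0)
  expect_equal(same$p, 1)

  ex <- mannWhitney(1:3, 4:6, exact = TRUE)
  expect_equal(ex$U, 0)
  expect_equal(ex$p, 0.1)                  # 2 of 20 splits
  expect_equal(mean(mwPermutationOracle(1:3, 4:6) <= ex$U), 0.1)

  expect_error(mannWhitney(numeric(0), 1:3), "empty")
})

test_that("U is invariant under monotone transforms and complements to nm", {
  set.seed(11)
  a <- rnorm(8); b <- rnorm(6) + 0.5
  u1 <- mannWhitney(a, b)
  u2 <- mannWhitney(exp(a), exp(b))
  expect_equal(u1$U, u2$U)
  expect_equal(u1$Z, u2$Z)
  # W of wilcox.test is U of the first sample; ours is the min of the pair
  w <- unname(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$statistic)
  expect_equal(u1$U, min(w, length(a) * length(b) - w))
  expect_equal(u1$p,
               stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("normal approximation tracks the exact permutation p at n = m = 10", {
  set.seed(21)
  a <- rnorm(10); b <- rnorm(10) + 0.9
  mw <- mannWhitney(a, b)
  # independent enumeration of all C(20, 10) splits
  rk <- rank(c(a, b))
  splits <- utils::combn(20, 10)
  ua <- colSums(matrix(rk[splits], nrow = 10)) - 55
  uDist <- pmin(ua, 100 - ua)
  pExact <- mean(uDist <= mw$U + 1e-9)
  expect_lt(abs(mw$p - pExact), 0.02)
})

test_that("KW with two groups matches the squared MW statistic at n = m = 50", {
  set.seed(31)
  a <- rnorm(50); b <- rnorm(50) + 0.4
  h <- kruskalWallis(list(a, b))$H
  z <- mannWhitney(a, b)$Z
  expect_equal(h / z^2, 1, tolerance = 0.05)
})

test_that("the hierarchical report gates pairwise tests on the global p", {
  f <- seq(0, 2.2, by = 0.1)
  mk <- function(shift) FrequencySeries(f, exp(-f) + shift,
                                        plane = "object", quantity = "eDQE")
  identical3 <- list(s1 = mk(0), s2 = mk(0), s3 = mk(0))
  rep0 <- pairwiseReport(identical3, FreqBinSpec("eDQE"))
  expect_equal(nrow(rep0@pairwise), 0)
  expect_true(all(rep0@kruskal$df == 2))

  shifted <- list(s1 = mk(0), s2 = mk(0.001), s3 = mk(0.7))
  rep1 <- pairwiseReport(shifted, FreqBinSpec("eDQE"))
  expect_true(all(rep1@kruskal$df == 2))
  expect_equal(rep1@kruskal$n[rep1@kruskal$bin == "low"], 33)
  lowPw <- rep1@pairwise[rep1@pairwise$bin == "low", ]
  expect_equal(nrow(lowPw), 3)
  # the uniformly shifted system separates completely from both others
  expect_equal(lowPw$U[grepl("s3", lowPw$pair)], c(0, 0))

  bad <- list(s1 = mk(0), s2 = mk(0),
              s3 = FrequencySeries(seq(0, 2.2, by = 0.2), rep(1, 12),
                                   plane = "object", quantity = "eDQE"))
  expect_error(pairwiseReport(bad), "mismatched")
})
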