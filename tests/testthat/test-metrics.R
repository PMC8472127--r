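mkMeasurement <- function(f = seq(0, 2, by = 0.1),
                          mtf = NULL, nnps = NULL, sf = 0.1, tf = 0.12,
                          ak = 16, q = 3e4) {
  if (is.null(mtf)) mtf <- exp(-0.5 * f)
  if (is.null(nnps)) nnps <- rep(2e-4, length(f))
  SystemMeasurement(
    FrequencySeries(f, mtf, plane = "object", quantity = "eMTF"),
    FrequencySeries(f, nnps, plane = "object", quantity = "eNNPS"),
    sf = sf, tf = tf, akUGy = ak, qPerUGyMm2 = q)
}

test_that("common-grid resampling reproduces the pooled sample counts", {
  f <- seq(0, 3, by = 0.05)
  cv <- FrequencySeries(f, exp(-f), plane = "object", quantity = "eMTF")
  out <- resampleCommonGrid(list(cv, cv, cv), step = 0.1, fmax = 1.0)
  expect_length(frequencies(out[[1]]), 11)
  expect_equal(sum(lengths(lapply(out, seriesValues))), 33)

  out2 <- resampleCommonGrid(list(cv, cv, cv), step = 0.1, fmax = 1.25)
  expect_length(frequencies(out2[[1]]), 13)
  expect_equal(sum(lengths(lapply(out2, seriesValues))), 39)

  onGrid <- FrequencySeries(seq(0, 1, by = 0.1), seq(1, 0, by = -0.1),
                            plane = "object", quantity = "eMTF")
  expect_equal(seriesValues(resampleCommonGrid(list(onGrid),
                                               step = 0.1)[[1]]),
               seriesValues(onGrid), tolerance = 1e-12)

  shortCurve <- FrequencySeries(seq(0, 0.5, by = 0.1), rep(1, 6),
                                plane = "object", quantity = "eNNPS")
  expect_error(resampleCommonGrid(list(cv, shortCurve), fmax = 1),
               "eNNPS")
})

test_that("eNEQ composes by direct substitution", {
  f <- seq(0, 1, by = 0.1)
  m <- mkMeasurement(f, mtf = rep(1, 11), nnps = rep(1e-6, 11), sf = 0)
  expect_equal(seriesValues(eneq(m)), rep(1e6, 11))

  mHalf <- mkMeasurement(f, mtf = rep(1, 11), nnps = rep(1e-6, 11), sf = 0.5)
  expect_equal(seriesValues(eneq(mHalf)), rep(2.5e5, 11))  # (1-SF)^2 factor
})

test_that("eDQE is eNEQ over TF*AK*q and the identity holds to machine precision", {
  f <- seq(0, 2, by = 0.1)
  denomTarget <- 0.12 * 16 * 3e4
  m <- mkMeasurement(f, mtf = rep(1, length(f)),
                     nnps = rep((1 - 0)^2 / denomTarget, length(f)), sf = 0)
  expect_equal(seriesValues(edqe(m)), rep(1, length(f)), tolerance = 1e-12)

  set.seed(3)
  m2 <- mkMeasurement(f, mtf = exp(-0.7 * f),
                      nnps = 2e-4 * (1 + 0.5 * runif(length(f))),
                      sf = 0.22, tf = 0.14, ak = 15.7, q = 28000)
  lhs <- seriesValues(eneq(m2))
  rhs <- seriesValues(edqe(m2)) * 0.14 * 15.7 * 28000
  expect_lt(max(abs(lhs - rhs)) / max(lhs), 1e-12)
})

test_that("eDQE responds monotonically to SF and eNNPS perturbations", {
  f <- seq(0, 2, by = 0.1)
  base <- mkMeasurement(f, sf = 0.1)
  moreScatter <- mkMeasurement(f, sf = 0.3)
  expect_true(all(seriesValues(edqe(moreScatter)) <
                  seriesValues(edqe(base))))
  lessNoise <- mkMeasurement(f, nnps = rep(1e-4, length(f)), sf = 0.1)
  expect_true(all(seriesValues(edqe(lessNoise)) >
                  seriesValues(edqe(base))))
})

test_that("non-positive eNNPS points are masked, not propagated", {
  f <- seq(0, 1, by = 0.1)
  nnps <- rep(2e-4, 11); nnps[4] <- 0
  m <- mkMeasurement(f, nnps = nnps)
  expect_warning(nq <- eneq(m), "masking")
  expect_true(is.na(seriesValues(nq)[4]))
  expect_equal(sum(is.na(seriesValues(nq))), 1)

  nnpsBad <- rep(0, 11); nnpsBad[1:2] <- 2e-4
  mBad <- mkMeasurement(f, nnps = nnpsBad)
  expect_error(eneq(mBad), "20%")
})

test_that("maxPeak finds the highest point with lowest-frequency ties", {
  dec <- FrequencySeries(seq(0, 1, by = 0.1), seq(1, 0, by = -0.1),
                         plane = "object", quantity = "eDQE")
  expect_equal(unname(maxPeak(dec)), c(0, 1))

  tri <- FrequencySeries(c(0, 0.1, 0.2), c(0.5, 0.9, 0.7),
                         plane = "object", quantity = "eDQE")
  expect_equal(unname(maxPeak(tri)), c(0.1, 0.9))

  tie <- FrequencySeries(c(0, 0.1, 0.2), c(0.4, 0.9, 0.9),
                         plane = "object", quantity = "eDQE")
  expect_equal(unname(maxPeak(tie))[1], 0.1)
})

test_that("mismatched grids are rejected at composition", {
  f1 <- seq(0, 1, by = 0.1)
  f2 <- seq(0, 2, by = 0.2)
  expect_error(SystemMeasurement(
    FrequencySeries(f1, rep(1, 11), "object", "eMTF"),
    FrequencySeries(f2, rep(1e-4, 11), "object", "eNNPS"),
    sf = 0.1, tf = 0.1, akUGy = 10, qPerUGyMm2 = 3e4), "identical")
})
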