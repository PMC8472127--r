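test_that("edge angle is recovered within 0.05 degrees on noise-free edges", {
  for (ang in c(3, 5)) {
    ke <- makeEdgeImage(ang, 0.15, 0.143, c(300, 300), noiseSd = 0, seed = 1)
    expect_equal(estimateEdgeAngle(ke$image), ang, tolerance = 0.05 / ang)
  }
})

test_that("a constant image raises an edge-detection error", {
  flat <- RadiographImage(matrix(500, 64, 64), 0.143)
  expect_error(estimateEdgeAngle(flat), "edge-detection")
})

test_that("super-sampled ESF matches the aperture-integrated erf oracle", {
  pitch <- 0.143
  sigma <- 0.2
  ke <- makeEdgeImage(3, sigma, pitch, c(400, 400), contrast = c(100, 1000),
                      noiseSd = 0, seed = 1)
  cfg <- EdgeAnalysisConfig(roiSizeMm = 50, window = "none")
  esf <- buildEsf(extractCentralRoi(ke$image, 50), config = cfg)
  expect_equal(esf@binWidthMm, 0.1 * pitch)  # 0.0143 mm bins at this pitch
  th <- 3 * pi / 180
  sel <- abs(esf@positionsMm) < 3
  truth <- 100 + 900 * esfQuadOracle(esf@positionsMm[sel], sigma,
                                     pitch * cos(th), pitch * sin(th))
  expect_lt(max(abs(esf@values[sel] - truth)) / 900, 0.005)
})

test_that("a sigma-0 edge yields a step ESF within one bin width", {
  ke <- makeEdgeImage(3, 0, 0.143, c(300, 300), contrast = c(0, 1000),
                      noiseSd = 0, seed = 1)
  esf <- buildEsf(extractCentralRoi(ke$image, 40),
                  config = EdgeAnalysisConfig(roiSizeMm = 40))
  v <- esf@values
  # transition from <10% to >90% of the step spans the pixel aperture
  lo <- max(esf@positionsMm[v < 100])
  hi <- min(esf@positionsMm[v > 900])
  expect_lt(hi - lo, 1.2 * 0.143 + 2 * esf@binWidthMm)
})

test_that("ESF differentiation behaves on canonical profiles", {
  h <- 0.01
  pos <- seq(-1, 1, by = h)
  step <- as.numeric(pos >= 0)
  esf <- new("EsfProfile", positionsMm = pos, values = step,
             binCounts = rep(1, length(pos)), binWidthMm = h)
  lsf <- esfToLsf(esf, EdgeAnalysisConfig(window = "none"))
  expect_equal(sum(lsf$values) * h, 1, tolerance = 1e-12)  # unit area
  expect_equal(sum(lsf$values > 0), 2)  # central difference spreads over 2 bins

  ramp <- new("EsfProfile", positionsMm = pos, values = pos + 1,
              binCounts = rep(1, length(pos)), binWidthMm = h)
  lr <- esfToLsf(ramp, EdgeAnalysisConfig(window = "none"))
  expect_equal(lr$values, rep(1, length(lr$values)), tolerance = 1e-9)

  short <- new("EsfProfile", positionsMm = c(0, h), values = c(0, 1),
               binCounts = c(1, 1), binWidthMm = h)
  expect_error(esfToLsf(short), "3 bins")
})

test_that("erf-profile ESF differentiates to a Gaussian of the right width", {
  h <- 0.0143
  pos <- seq(-3, 3, by = h)
  esf <- new("EsfProfile", positionsMm = pos, values = pnorm(pos / 0.2),
             binCounts = rep(1, length(pos)), binWidthMm = h)
  lsf <- esfToLsf(esf, EdgeAnalysisConfig(window = "none"))
  w <- lsf$values / sum(lsf$values)
  mu <- sum(w * lsf$positionsMm)
  sigmaHat <- sqrt(sum(w * (lsf$positionsMm - mu)^2))
  expect_equal(sigmaHat, 0.2, tolerance = 0.02)
})

test_that("MTF is 1 at zero frequency and matches the Gaussian closed form", {
  h <- 0.0143
  pos <- seq(-3, 3, by = h)
  lsf <- list(positionsMm = pos, values = dnorm(pos, sd = 0.2),
              binWidthMm = h)
  mtf <- lsfToMtf(lsf, maxFreq = 2.5)
  expect_equal(seriesValues(mtf)[1], 1)
  truth <- exp(-2 * pi^2 * 0.04 * frequencies(mtf)^2)
  rms <- sqrt(mean((seriesValues(mtf) - truth)^2))
  expect_lt(rms, 0.02)

  posI <- (-200:200) * h
  impulse <- list(positionsMm = posI, values = as.numeric(posI == 0),
                  binWidthMm = h)
  mi <- lsfToMtf(impulse, maxFreq = 2.5)
  expect_equal(seriesValues(mi), rep(1, length(frequencies(mi))))
  expect_error(lsfToMtf(list(positionsMm = pos,
                             values = rep(0, length(pos)),
                             binWidthMm = h)), "normalization")
})

test_that("averaging and object-plane projection follow the magnification", {
  f <- seq(0, 3, by = 0.05)
  cv <- FrequencySeries(f, exp(-f), plane = "detector", quantity = "eMTF")
  five <- replicate(5, cv)
  geomId <- GeometrySetup(130, 130, 0, "cone", "measured_axis")  # m = 1
  avg <- averageAndProject(five, geomId, step = 0.05)
  expect_equal(seriesValues(avg), exp(-frequencies(avg)), tolerance = 1e-9)
  expect_identical(plane(avg), "object")

  geomM <- GeometrySetup(130, 130, 13, "cone", "measured_axis")
  expect_equal(magnification(geomM), 1.11111, tolerance = 1e-5)
  prj <- averageAndProject(list(cv), geomM, step = 0.1)
  i <- which.min(abs(frequencies(prj) / magnification(geomM) - 1))
  expect_equal(frequencies(prj)[i], 1.11111, tolerance = 1e-4)

  slot <- GeometrySetup(130, 130, 13, "slot", "none")
  expect_equal(magnification(slot), 1)

  obj <- FrequencySeries(f, exp(-f), plane = "object", quantity = "eMTF")
  expect_error(averageAndProject(list(obj), geomId), "detector")
})

test_that("full edge pipeline recovers the analytic MTF and is monotone", {
  pitch <- 0.143
  sigma <- 0.2
  edges <- lapply(1:5, function(i) {
    makeEdgeImage(3, sigma, pitch, c(400, 400), contrast = c(100, 1000),
                  noiseSd = 4.5, seed = 10 + i,
                  edgeShiftMm = (i - 3) * 0.3)$image
  })
  cfg <- EdgeAnalysisConfig(roiSizeMm = 50)   # hann window + compensation on
  mtf <- estimateEmtf(edges, cfg, GeometrySetup(100))
  f <- frequencies(mtf); v <- seriesValues(mtf)
  expect_equal(v[1], 1)
  nyq <- 1 / (2 * pitch)
  sel <- f <= 0.8 * nyq
  truth <- analyticEdgeMtf(f, sigma, pitch)
  expect_lt(sqrt(mean((v[sel] - truth[sel])^2)), 0.03)
  expect_true(all(diff(v[sel]) < 0.01))  # non-increasing up to noise
})
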