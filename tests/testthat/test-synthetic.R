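test_that("flat-field generator matches its closed-form NNPS truth", {
  const <- makeFlatField(1000, 0, 0.1, c(32, 32), seed = 1)
  expect_true(all(pixels(const$image) == 1000))
  expect_equal(const$truth@trueNnpsLevelMm2, 0)

  ff <- makeFlatField(1000, 10, 0.1, c(64, 64), seed = 2)
  expect_equal(ff$truth@trueNnpsLevelMm2, 1e-6)  # sigma^2 dx^2 / mu^2

  expect_error(makeFlatField(1000, -1, 0.1, c(32, 32)), "noiseSd")
})

test_that("generators are deterministic under a fixed seed", {
  a <- makeFlatField(1000, 10, 0.1, c(64, 64), seed = 42)$image
  b <- makeFlatField(1000, 10, 0.1, c(64, 64), seed = 42)$image
  expect_identical(pixels(a), pixels(b))

  e1 <- makeEdgeImage(3, 0.2, 0.143, c(64, 64), noiseSd = 5, seed = 9)$image
  e2 <- makeEdgeImage(3, 0.2, 0.143, c(64, 64), noiseSd = 5, seed = 9)$image
  expect_identical(pixels(e1), pixels(e2))

  s1 <- makeExposureSeries("linear", c(0, 2), 1:10, noiseSd = 3, seed = 5)
  s2 <- makeExposureSeries("linear", c(0, 2), 1:10, noiseSd = 3, seed = 5)
  expect_identical(pixels(s1$images[[4]]), pixels(s2$images[[4]]))
})

test_that("sharp noise-free edge is binary away from the edge band", {
  ke <- makeEdgeImage(3, 0, 0.143, c(128, 128), contrast = c(100, 1000),
                      noiseSd = 0, seed = 1)
  px <- pixels(ke$image)
  away <- abs(px - 100) > 1 & abs(px - 1000) > 1
  # only pixels cut by the edge line are intermediate
  expect_lt(mean(away), 0.03)
  expect_equal(ke$truth@trueMtfSigmaMm, 0)
  expect_equal(sort(unique(round(range(px)))), c(100, 1000))
})

test_that("edge truth records the requested PSF and angle", {
  ke <- makeEdgeImage(3, 0.2, 0.1, c(64, 64), seed = 1)
  expect_equal(ke$truth@trueMtfSigmaMm, 0.2)
  expect_equal(ke$truth@trueEdgeAngleDeg, 3)
  expect_error(makeEdgeImage(0.2, 0.2, 0.1, c(64, 64)), "angleDeg")
  expect_error(makeEdgeImage(20, 0.2, 0.1, c(64, 64)), "angleDeg")
})

test_that("beam-stop truth is the exact signal ratio", {
  g <- BeamStopGridSpec(11, 11, pitchMm = 6, cylinderDiameterMm = 2)
  clean <- makeBeamStopImage(g, 700, 0, 0, pitchMm = 0.2,
                             shape = c(340, 340), seed = 1)
  expect_equal(clean$truth@trueSf, 0)

  bs <- makeBeamStopImage(g, 700, 300, 0, pitchMm = 0.2,
                          shape = c(340, 340), seed = 1)
  expect_equal(bs$truth@trueSf, 0.3)

  leaky <- makeBeamStopImage(g, 700, 300, 0.1, pitchMm = 0.2,
                             shape = c(340, 340), seed = 1)
  expect_equal(leaky$truth@trueSf, (700 * 0.1 + 300) / 1000)

  expect_error(makeBeamStopImage(g, 700, 0, 0, pitchMm = 0.2,
                                 shape = c(100, 100)), "fit")
})

test_that("an 11 x 11 grid renders 121 separable shadows", {
  g <- BeamStopGridSpec(11, 11, pitchMm = 8, cylinderDiameterMm = 2.4)
  bs <- makeBeamStopImage(g, 700, 300, 0, pitchMm = 0.25,
                          shape = c(380, 380), seed = 1)
  # auto detection labels the shadows and errors unless exactly 121 found
  res <- measureScatterFraction(bs$image, "auto")
  expect_equal(res@nCylindersUsed, 25)
  px <- pixels(bs$image)
  areaPerDisk <- sum(px < 500) / 121
  expect_equal(areaPerDisk, pi * (1.2 / 0.25)^2, tolerance = 0.05)
})

test_that("exposure series evaluates the response at each dose level", {
  ser <- makeExposureSeries("linear", c(5, 2), 1:10, shape = c(16, 16),
                            noiseSd = 0, seed = 1)
  expect_length(ser$images, 10)
  means <- vapply(ser$images, function(im) mean(pixels(im)), numeric(1))
  expect_equal(means, seq(7, 25, by = 2))
  expect_equal(ser$truth@responseCoeffs, c(5, 2))

  quint <- makeExposureSeries("polynomial5", c(0, 0, 0, 0, 0, 0.001), 1:10,
                              shape = c(8, 8), noiseSd = 0, seed = 1)
  qm <- vapply(quint$images, function(im) mean(pixels(im)), numeric(1))
  expect_true(all(diff(qm) > 0))

  expect_error(makeExposureSeries("linear", c(5, -2), 1:10),
               "increasing")
})

test_that("generated spectra vanish above the tube voltage and harden under filtration", {
  s <- makeSpectrum(90, 0, 0)
  expect_true(all(s@fluencePerMm2[s@energiesKev >= 90] == 0))
  expect_true(all(s@fluencePerMm2 >= 0))

  meanE <- function(sp) sum(sp@energiesKev * sp@fluencePerMm2) /
    sum(sp@fluencePerMm2)
  expect_gt(meanE(makeSpectrum(90, 0, 0.1)), meanE(makeSpectrum(90, 0, 0)))
  expect_error(makeSpectrum(8), "kvp")
})

test_that("spectrum CSV round-trips", {
  s <- makeSpectrum(70, 0, 0.1)
  f <- tempfile(fileext = ".csv")
  writeSpectrum(s, f)
  rt <- readSpectrum(f)
  expect_equal(rt@energiesKev, s@energiesKev)
  expect_equal(rt@fluencePerMm2, s@fluencePerMm2)
})
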