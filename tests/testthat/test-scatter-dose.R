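test_that("scatter fraction is recovered from noise-free beam-stop images", {
  g <- BeamStopGridSpec(11, 11, pitchMm = 6, cylinderDiameterMm = 2)
  bs <- makeBeamStopImage(g, 700, 300, 0, pitchMm = 0.2,
                          shape = c(340, 340), seed = 1)
  res <- measureScatterFraction(bs$image, g)
  expect_equal(scatterFraction(res), 0.3, tolerance = 0.005 / 0.3)
  expect_lt(abs(scatterFraction(res) - 0.3), 0.003)  # rasterization only
  expect_equal(res@nCylindersUsed, 25)
  expect_equal(res@sf, res@mpvLead / res@mpvBackground)

  clean <- makeBeamStopImage(g, 700, 0, 0, pitchMm = 0.2,
                             shape = c(340, 340), seed = 1)
  expect_equal(scatterFraction(measureScatterFraction(clean$image, g)), 0)
})

test_that("auto-detected grids agree with the known geometry", {
  g <- BeamStopGridSpec(11, 11, pitchMm = 6, cylinderDiameterMm = 2,
                        centerOffsetMm = c(1.5, -2))
  bs <- makeBeamStopImage(g, 700, 300, 0, noiseSd = 5, pitchMm = 0.2,
                          shape = c(360, 360), seed = 4)
  explicit <- measureScatterFraction(bs$image, g)
  auto <- measureScatterFraction(bs$image, "auto")
  expect_equal(scatterFraction(auto), scatterFraction(explicit),
               tolerance = 0.01)
})

test_that("scatter estimate stays within 0.01 of truth under 1 percent noise", {
  g <- BeamStopGridSpec(11, 11, pitchMm = 5, cylinderDiameterMm = 1.5)
  errs <- vapply(1:20, function(s) {
    bs <- makeBeamStopImage(g, 700, 300, 0, noiseSd = 10, pitchMm = 0.2,
                            shape = c(300, 300), seed = s)
    scatterFraction(measureScatterFraction(bs$image, g)) - 0.3
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.01)
})

test_that("transmission factor is the reading ratio with guarded bounds", {
  expect_equal(transmissionFactor(DoseReadings(10, 10, 100, 100)), 1)
  expect_equal(transmissionFactor(DoseReadings(1.2, 10, 100, 100)), 0.12)
  expect_error(DoseReadings(11, 10, 100, 100), "exceed")
  expect_error(DoseReadings(0, 10, 100, 100), "positive")
})

test_that("incident air kerma follows linear or inverse-square falloff", {
  slotEq <- DoseReadings(5, 10, sddCm = 100, sidCm = 100, beamMode = "slot")
  coneEq <- DoseReadings(5, 10, sddCm = 100, sidCm = 100, beamMode = "cone")
  expect_equal(incidentAirKerma(10, slotEq), 10)   # SDD = SID identity
  expect_equal(incidentAirKerma(10, coneEq), 10)

  slotHalf <- DoseReadings(5, 10, sddCm = 50, sidCm = 100, beamMode = "slot")
  coneHalf <- DoseReadings(5, 10, sddCm = 50, sidCm = 100, beamMode = "cone")
  expect_equal(incidentAirKerma(8, slotHalf), 4)
  expect_equal(incidentAirKerma(8, coneHalf), 2)

  ldss <- DoseReadings(5, 10, sddCm = 65, sidCm = 130, beamMode = "slot")
  expect_equal(incidentAirKerma(10, ldss), 5)

  # linear falloff dominates the quadratic one whenever SDD < SID
  set.seed(2)
  for (i in 1:25) {
    sid <- runif(1, 100, 300)
    sdd <- runif(1, 20, sid)
    ak <- runif(1, 1, 30)
    s <- incidentAirKerma(ak, DoseReadings(1, 2, sdd, sid, "slot"))
    cn <- incidentAirKerma(ak, DoseReadings(1, 2, sdd, sid, "cone"))
    expect_gte(s, cn)
  }
})

test_that("detector air kerma reproduces the worked dose examples", {
  expect_equal(round(detectorAirKerma(16.40, 0.12), 2), 1.97)
  expect_equal(detectorAirKerma(10, 1), 10)
  expect_equal(round(detectorAirKerma(15.68, 0.11), 2), 1.72)
  expect_error(detectorAirKerma(10, 0), "TF")
  expect_error(detectorAirKerma(10, 1.2), "TF")
})

test_that("SF and TF are dimensionless and bounded on valid inputs", {
  set.seed(5)
  for (i in 1:20) {
    akm <- runif(1, 1, 20)
    tf <- transmissionFactor(DoseReadings(akm, akm + runif(1, 0, 30),
                                          80, 100))
    expect_true(tf > 0 && tf <= 1)
  }
  g <- BeamStopGridSpec(11, 11, pitchMm = 5, cylinderDiameterMm = 1.5)
  for (sfTrue in c(0.1, 0.25, 0.4)) {
    bs <- makeBeamStopImage(g, 1000 * (1 - sfTrue), 1000 * sfTrue, 0,
                            pitchMm = 0.2, shape = c(300, 300), seed = 2)
    sf <- scatterFraction(measureScatterFraction(bs$image, g))
    expect_true(sf >= 0 && sf < 1)
    expect_lt(abs(sf - sfTrue), 0.003)
  }
})
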