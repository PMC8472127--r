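test_that("sub-ROI tiling counts follow the overlap arithmetic", {
  img1024 <- makeFlatField(1000, 5, 0.1, c(1024, 1024), seed = 1)$image
  expect_length(extractSubrois(img1024, NnpsConfig()), 49)

  img512 <- makeFlatField(1000, 5, 0.1, c(512, 512), seed = 1)$image
  expect_length(extractSubrois(img512, NnpsConfig(roiPx = 512)), 9)
  expect_length(extractSubrois(img512,
    NnpsConfig(roiPx = 256, subPx = 256, overlapPx = 128)), 1)

  small <- makeFlatField(1000, 5, 0.1, c(64, 64), seed = 1)$image
  expect_error(extractSubrois(small, NnpsConfig()), "scaled-down")
  expect_error(NnpsConfig(roiPx = 1000), "divisible")
})

test_that("white-noise NNPS sits at the closed-form plateau", {
  cfg <- NnpsConfig(roiPx = 512)
  flats <- makeFlatSet(4, mean = 1000, sd = 10, pitch = 0.1, side = 520)
  n2 <- nnps2d(flats, cfg)
  truth <- 1e-6  # sigma^2 dx^2 / mu^2
  offAxis <- n2@nnps[, abs(n2@u) > 1e-9]
  expect_equal(mean(offAxis), truth, tolerance = 0.05)
  c1 <- nnps1dVertical(n2, cfg)
  expect_equal(mean(seriesValues(c1)[-1]), truth, tolerance = 0.05)
  # isotropic white noise -> flat 1D curve
  expect_lt(stats::sd(seriesValues(c1)[-1]) / mean(seriesValues(c1)[-1]),
            0.15)
})

test_that("a noise-free constant image has zero NNPS", {
  cfg <- NnpsConfig(roiPx = 256, subPx = 128, overlapPx = 64)
  img <- RadiographImage(matrix(1000, 260, 260), 0.1, linearized = TRUE)
  n2 <- nnps2d(list(img), cfg)
  expect_true(all(n2@nnps < 1e-20))
})

test_that("the NPS integral satisfies Parseval", {
  cfg <- NnpsConfig(roiPx = 256, detrend = "mean")
  flats <- makeFlatSet(2, mean = 500, sd = 8, pitch = 0.2, side = 260,
                       seedBase = 40)
  n2 <- nnps2d(flats, cfg)
  df <- 1 / (cfg@subPx * 0.2)
  integral <- sum(n2@nnps) * df^2 * n2@meanSignal^2
  # independent variance oracle: mean per-sub-ROI variance
  vars <- unlist(lapply(flats, function(im)
    vapply(extractSubrois(im, cfg), function(s) mean((s - mean(s))^2),
           numeric(1))))
  expect_equal(integral, mean(vars), tolerance = 0.02)
})

test_that("NNPS is invariant to a global gain", {
  cfg <- NnpsConfig(roiPx = 256)
  flats <- makeFlatSet(2, mean = 800, sd = 6, pitch = 0.15, side = 260,
                       seedBase = 60)
  n2a <- nnps2d(flats, cfg)
  scaled <- lapply(flats, function(im)
    RadiographImage(pixels(im) * 3.7, pixelPitch(im), linearized = TRUE))
  n2b <- nnps2d(scaled, cfg)
  expect_lt(max(abs(n2b@nnps - n2a@nnps)) / max(n2a@nnps), 1e-10)
})

test_that("the on-axis column is excluded from the 1D average", {
  cfg <- NnpsConfig(roiPx = 256)
  flats <- makeFlatSet(2, mean = 800, sd = 6, pitch = 0.15, side = 260,
                       seedBase = 80)
  n2 <- nnps2d(flats, cfg)
  base <- nnps1dVertical(n2, cfg)
  inflated <- n2
  center <- length(inflated@u) %/% 2 + 1
  inflated@nnps[, center] <- inflated@nnps[, center] * 1e6  # trend leakage
  withAxisExcluded <- nnps1dVertical(inflated, cfg)
  expect_equal(seriesValues(withAxisExcluded), seriesValues(base))
  cfgIn <- NnpsConfig(roiPx = 256, excludeAxis = FALSE)
  withAxis <- nnps1dVertical(inflated, cfgIn)
  expect_gt(mean(seriesValues(withAxis)), 10 * mean(seriesValues(base)))
})

test_that("object-plane projection rescales the frequency step", {
  cfg <- NnpsConfig(roiPx = 256, subPx = 128, overlapPx = 64)
  flats <- makeFlatSet(1, mean = 800, sd = 6, pitch = 0.15, side = 260,
                       seedBase = 90)
  n2 <- nnps2d(flats, cfg)
  det <- nnps1dVertical(n2, cfg)
  geom <- GeometrySetup(130, 130, 13, "cone", "measured_axis")  # m = 1.111
  obj <- nnps1dVertical(n2, cfg, geom)
  expect_equal(frequencies(obj)[2] / frequencies(det)[2],
               magnification(geom), tolerance = 1e-9)
  expect_identical(plane(obj), "object")
  expect_equal(seriesValues(obj), seriesValues(det))
})

test_that("Poisson noise halves NNPS when dose doubles", {
  cfg <- NnpsConfig(roiPx = 256, subPx = 128, overlapPx = 64)
  lvl <- function(mean, seeds) {
    flats <- lapply(seeds, function(s)
      makeFlatField(mean, 0, 0.1, c(260, 260), seed = s,
                    noiseModel = "poisson")$image)
    c1 <- nnps1dVertical(nnps2d(flats, cfg), cfg)
    mean(seriesValues(c1)[-1])
  }
  lo <- lvl(1000, 1:3)
  hi <- lvl(4000, 4:6)
  expect_equal(lo / hi, 4, tolerance = 0.1)
})

test_that("estimator spread shrinks with the number of sub-ROIs", {
  est <- function(cfg, side, seed) {
    flats <- makeFlatSet(1, mean = 1000, sd = 10, pitch = 0.1, side = side,
                         seedBase = seed * 17)
    c1 <- nnps1dVertical(nnps2d(flats, cfg), cfg)
    mean(seriesValues(c1)[-1])
  }
  cfgSmall <- NnpsConfig(roiPx = 128, subPx = 64, overlapPx = 32,
                         bandLines = 3)      # 9 sub-ROIs
  cfgBig <- NnpsConfig(roiPx = 320, subPx = 64, overlapPx = 32,
                       bandLines = 3)        # 81 sub-ROIs
  sdSmall <- stats::sd(vapply(1:8, function(s) est(cfgSmall, 140, s),
                              numeric(1)))
  sdBig <- stats::sd(vapply(1:8, function(s) est(cfgBig, 330, s + 50),
                            numeric(1)))
  expect_lt(sdBig, sdSmall)
})
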