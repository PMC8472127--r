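# Synthetic radiograph generators with closed-form ground truth. The study
# conditions they emulate: flat fields of a homogeneous phantom (eNNPS
# input, 4 images), a tungsten edge at a 3 degree tilt (eMTF input, 5
# images at high exposure), an 11 x 11 lead beam-stop grid (scatter
# fraction input) and a 10-level exposure series (detector response
# input). Noise is additive Gaussian by default: every downstream
# estimator consumes only second-order statistics, so Gaussian noise gives
# exact closed-form NNPS truth. A Poisson option exists for physics sanity
# checks.

#' Generate a flat-field image
#'
#' Homogeneous phantom exposure: constant level plus an optional smooth 2D
#' quadratic trend (heel-effect stand-in) plus i.i.d. noise. The recorded
#' ground-truth NNPS level is the white-noise plateau
#' \eqn{\sigma^2 \Delta x^2 / \mu^2} in mm^2.
#'
#' @param meanLevel mean pixel level (kerma-proportional units), positive.
#' @param noiseSd Gaussian noise standard deviation, >= 0 (ignored for
#'   \code{noiseModel = "poisson"}).
#' @param pitchMm pixel pitch, mm.
#' @param shape integer (rows, cols).
#' @param trendAmplitude amplitude of the quadratic trend (value added at
#'   the ROI corners relative to the center).
#' @param seed RNG seed.
#' @param noiseModel \code{"gaussian"} (default) or \code{"poisson"}
#'   (pixel ~ Poisson(meanLevel + trend)).
#' @param meta optional \linkS4class{AcquisitionMeta}.
#' @return list(image = \linkS4class{RadiographImage},
#'   truth = \linkS4class{SyntheticGroundTruth}).
#' @examples
#' ff <- makeFlatField(1000, 10, 0.1, c(64, 64), seed = 1)
#' ff$truth@trueNnpsLevelMm2  # 1e-6 mm^2
#' @export
makeFlatField <- function(meanLevel, noiseSd, pitchMm, shape,
                          trendAmplitude = 0, seed = 1,
                          noiseModel = c("gaussian", "poisson"),
                          meta = AcquisitionMeta()) {
  noiseModel <- match.arg(noiseModel)
  if (noiseSd < 0) stopf("validation error: noiseSd must be >= 0")
  if (meanLevel <= 0) stopf("meanLevel must be positive")
  nr <- shape[1]; nc <- shape[2]
  u <- (seq_len(nr) - (nr + 1) / 2) / ((nr - 1) / 2)
  v <- (seq_len(nc) - (nc + 1) / 2) / ((nc - 1) / 2)
  trend <- trendAmplitude * (outer(u^2, rep(1, nc)) +
                             outer(rep(1, nr), v^2)) / 2
  px <- withSeed(seed, {
    if (noiseModel == "poisson") {
      matrix(stats::rpois(nr * nc, lambda = as.vector(meanLevel + trend)),
             nr, nc)
    } else {
      meanLevel + trend +
        matrix(stats::rnorm(nr * nc, sd = noiseSd), nr, nc)
    }
  })
  px <- pmax(px, 0)
  lvl <- if (noiseModel == "poisson") meanLevel * pitchMm^2 / meanLevel^2
         else noiseSd^2 * pitchMm^2 / meanLevel^2
  truth <- new("SyntheticGroundTruth", trueNnpsLevelMm2 = lvl,
               seed = as.numeric(seed))
  list(image = RadiographImage(px, pitchMm, linearized = TRUE, meta = meta),
       truth = truth)
}

# Repeated integral of the standard normal CDF: G1' = pnorm, G2' = G1.
.G1 <- function(z) z * stats::pnorm(z) + stats::dnorm(z)
.G2 <- function(z) ((z^2 + 1) * stats::pnorm(z) + z * stats::dnorm(z)) / 2
# sigma = 0 limits (hard step).
.Q2 <- function(z) pmax(z, 0)^2 / 2

# Mean over a w1 x w2 box of the sigma-blurred unit step at signed
# center-distance d: exact pixel-aperture integration of the erf profile.
.boxBlurredStep <- function(d, sigma, w1, w2) {
  h1 <- w1 / 2; h2 <- w2 / 2
  if (sigma > 0) {
    (sigma^2 / (w1 * w2)) *
      (.G2((d + h1 + h2) / sigma) - .G2((d + h1 - h2) / sigma) -
       .G2((d - h1 + h2) / sigma) + .G2((d - h1 - h2) / sigma))
  } else {
    (.Q2(d + h1 + h2) - .Q2(d + h1 - h2) -
     .Q2(d - h1 + h2) + .Q2(d - h1 - h2)) / (w1 * w2)
  }
}

#' Generate a slanted-edge image
#'
#' Ideal high-contrast step along a line tilted \code{angleDeg} from the
#' column (vertical) axis, convolved with an isotropic Gaussian PSF of
#' width \code{sigmaMm} and integrated analytically over each square pixel
#' aperture (no rasterization bias), plus optional Gaussian noise. The
#' analytic pre-sampled MTF of such an image is
#' \eqn{\exp(-2\pi^2\sigma^2 f^2)} times the pixel-aperture sinc.
#'
#' @param angleDeg edge tilt from the vertical axis, degrees; must lie in
#'   [0.5, 15] so that super-sampling is well conditioned.
#' @param sigmaMm Gaussian PSF sigma, mm, >= 0.
#' @param pitchMm pixel pitch, mm.
#' @param shape integer (rows, cols).
#' @param contrast c(low, high) pixel levels either side of the edge.
#' @param noiseSd Gaussian noise sd, >= 0.
#' @param seed RNG seed.
#' @param edgeShiftMm lateral shift of the edge from the image center, mm
#'   (the physical edge is shifted slightly between exposures).
#' @param meta optional \linkS4class{AcquisitionMeta}.
#' @return list(image, truth) as in \code{\link{makeFlatField}}; the truth
#'   records \code{trueMtfSigmaMm} and \code{trueEdgeAngleDeg}.
#' @export
makeEdgeImage <- function(angleDeg = 3, sigmaMm = 0.2, pitchMm = 0.143,
                          shape = c(256, 256), contrast = c(100, 1000),
                          noiseSd = 0, seed = 1, edgeShiftMm = 0,
                          meta = AcquisitionMeta()) {
  if (angleDeg < 0.5 || angleDeg > 15)
    stopf("validation error: angleDeg must lie in [0.5, 15]")
  if (sigmaMm < 0) stopf("validation error: sigmaMm must be >= 0")
  nr <- shape[1]; nc <- shape[2]
  th <- angleDeg * pi / 180
  x <- (seq_len(nc) - (nc + 1) / 2) * pitchMm   # horizontal, mm
  y <- (seq_len(nr) - (nr + 1) / 2) * pitchMm   # vertical (rows), mm
  # signed distance of each pixel center to the edge line
  d <- outer(-y * sin(th), x * cos(th), "+") - edgeShiftMm
  w1 <- pitchMm * cos(th)
  w2 <- pitchMm * sin(th)
  frac <- .boxBlurredStep(d, sigmaMm, w1, w2)
  px <- contrast[1] + (contrast[2] - contrast[1]) * frac
  if (noiseSd > 0)
    px <- px + withSeed(seed, matrix(stats::rnorm(nr * nc, sd = noiseSd),
                                     nr, nc))
  px <- pmax(px, 0)
  truth <- new("SyntheticGroundTruth", trueMtfSigmaMm = sigmaMm,
               trueEdgeAngleDeg = angleDeg, seed = as.numeric(seed))
  list(image = RadiographImage(px, pitchMm, linearized = TRUE, meta = meta),
       truth = truth)
}

#' Analytic MTF of a synthetic edge image
#'
#' The pre-sampled transfer of the generator: Gaussian PSF times the pixel
#' aperture, \eqn{\exp(-2\pi^2\sigma^2 f^2)\,|sinc(\pi f a)|} with
#' \eqn{a} the pixel pitch.
#'
#' @param f frequencies, mm^-1.
#' @param sigmaMm Gaussian PSF sigma, mm.
#' @param pitchMm pixel pitch, mm (set 0 to drop the aperture term).
#' @return numeric MTF values.
#' @export
analyticEdgeMtf <- function(f, sigmaMm, pitchMm = 0) {
  m <- exp(-2 * pi^2 * sigmaMm^2 * f^2)
  if (pitchMm > 0) m <- m * abs(sincx(pi * f * pitchMm))
  m
}

#' Generate a beam-stop grid image
#'
#' Renders the lead-cylinder grid as hard opaque disks: background pixels
#' carry primary + scatter, pixels inside a cylinder shadow carry
#' primary * leadTransmission + scatter. The ground-truth scatter fraction
#' is the exact ratio the analyzer should recover,
#' \eqn{(P\,t_{Pb} + S) / (P + S)}.
#'
#' @param grid a \linkS4class{BeamStopGridSpec}.
#' @param primaryLevel primary (unscattered) signal level, positive.
#' @param scatterLevel scatter signal level, >= 0.
#' @param leadTransmission residual transmission through the lead,
#'   in [0, 1).
#' @param noiseSd Gaussian noise sd, >= 0.
#' @param pitchMm pixel pitch, mm.
#' @param shape integer (rows, cols).
#' @param seed RNG seed.
#' @param meta optional \linkS4class{AcquisitionMeta}.
#' @return list(image, truth); the truth records \code{trueSf}.
#' @export
makeBeamStopImage <- function(grid, primaryLevel, scatterLevel = 0,
                              leadTransmission = 0, noiseSd = 0,
                              pitchMm = 0.143, shape = c(512, 512),
                              seed = 1, meta = AcquisitionMeta()) {
  validObject(grid)
  if (primaryLevel <= 0) stopf("primaryLevel must be positive")
  if (scatterLevel < 0) stopf("scatterLevel must be >= 0")
  if (leadTransmission < 0 || leadTransmission >= 1)
    stopf("leadTransmission must lie in [0, 1)")
  nr <- shape[1]; nc <- shape[2]
  extentR <- (grid@nRows - 1) * grid@pitchMm + grid@cylinderDiameterMm
  extentC <- (grid@nCols - 1) * grid@pitchMm + grid@cylinderDiameterMm
  if (extentR > nr * pitchMm || extentC > nc * pitchMm)
    stopf("validation error: grid extent (%.1f x %.1f mm) does not fit the %d x %d image",
          extentR, extentC, nr, nc)
  y <- (seq_len(nr) - (nr + 1) / 2) * pitchMm
  x <- (seq_len(nc) - (nc + 1) / 2) * pitchMm
  centers <- beamStopCenters(grid)
  inside <- matrix(FALSE, nr, nc)
  rad <- grid@cylinderDiameterMm / 2
  for (k in seq_len(nrow(centers))) {
    cy <- centers[k, 1]; cx <- centers[k, 2]
    ri <- which(abs(y - cy) <= rad)
    ci <- which(abs(x - cx) <= rad)
    if (!length(ri) || !length(ci)) next
    dd <- outer((y[ri] - cy)^2, (x[ci] - cx)^2, "+")
    inside[ri, ci] <- inside[ri, ci] | (dd <= rad^2)
  }
  bg <- primaryLevel + scatterLevel
  lead <- primaryLevel * leadTransmission + scatterLevel
  px <- matrix(bg, nr, nc)
  px[inside] <- lead
  if (noiseSd > 0)
    px <- px + withSeed(seed, matrix(stats::rnorm(nr * nc, sd = noiseSd),
                                     nr, nc))
  px <- pmax(px, 0)
  truth <- new("SyntheticGroundTruth", trueSf = lead / bg,
               seed = as.numeric(seed))
  list(image = RadiographImage(px, pitchMm, linearized = TRUE, meta = meta),
       truth = truth)
}

# Cylinder center coordinates (row mm, col mm) relative to image center.
beamStopCenters <- function(grid) {
  ro <- (seq_len(grid@nRows) - (grid@nRows + 1) / 2) * grid@pitchMm +
    grid@centerOffsetMm[1]
  co <- (seq_len(grid@nCols) - (grid@nCols + 1) / 2) * grid@pitchMm +
    grid@centerOffsetMm[2]
  cbind(rep(ro, times = grid@nCols), rep(co, each = grid@nRows))
}

# Evaluate a polynomial, intercept first.
.polyEval <- function(coeffs, x) {
  acc <- 0
  for (k in rev(seq_along(coeffs))) acc <- acc * x + coeffs[k]
  acc
}

#' Generate a detector-response exposure series
#'
#' One flat image per dose level, with mean pixel value equal to the
#' chosen response function evaluated at that level, plus additive noise.
#' The study acquires 10 dose levels per system.
#'
#' @param responseKind \code{"linear"} or \code{"polynomial5"}.
#' @param coeffs response polynomial coefficients, intercept first
#'   (length 2 for linear, up to 6 for polynomial5).
#' @param dakLevels detector-air-kerma levels, uGy; positive, distinct.
#' @param pitchMm pixel pitch, mm.
#' @param shape per-image (rows, cols).
#' @param noiseSd Gaussian noise sd, >= 0.
#' @param seed RNG seed.
#' @param meta optional \linkS4class{AcquisitionMeta}.
#' @return list(images = list of \linkS4class{RadiographImage},
#'   dakUGy = numeric, truth = \linkS4class{SyntheticGroundTruth}).
#' @export
makeExposureSeries <- function(responseKind = c("linear", "polynomial5"),
                               coeffs, dakLevels, pitchMm = 0.143,
                               shape = c(64, 64), noiseSd = 0, seed = 1,
                               meta = AcquisitionMeta()) {
  responseKind <- match.arg(responseKind)
  if (any(dakLevels <= 0)) stopf("dakLevels must be positive")
  grid <- seq(min(dakLevels), max(dakLevels), length.out = 512)
  if (any(diff(.polyEval(coeffs, grid)) <= 0))
    stopf("validation error: response is not strictly increasing over the dak range")
  means <- .polyEval(coeffs, dakLevels)
  images <- withSeed(seed, lapply(seq_along(dakLevels), function(i) {
    px <- means[i] + matrix(stats::rnorm(prod(shape), sd = noiseSd),
                            shape[1], shape[2])
    RadiographImage(pmax(px, 0), pitchMm, linearized = FALSE, meta = meta)
  }))
  truth <- new("SyntheticGroundTruth", responseCoeffs = as.numeric(coeffs),
               seed = as.numeric(seed))
  list(images = images, dakUGy = as.numeric(dakLevels), truth = truth)
}

# Shipped mass-attenuation tables (NIST tabulations, log-log interpolated).
.attenuationTable <- function(material = c("Al", "Cu")) {
  material <- match.arg(material)
  path <- system.file("extdata",
                      sprintf("mu_rho_%s.csv", tolower(material)),
                      package = "effiq")
  utils::read.csv(path, comment.char = "#")
}

#' Generate a filtered bremsstrahlung spectrum
#'
#' Kramers-form bremsstrahlung, fluence proportional to
#' \eqn{(kVp - E)/E}, truncated at the tube voltage and attenuated by
#' aluminium/copper filtration using shipped mass-attenuation tables.
#' A deliberately simple tube model: adequate for producing realistic
#' beam-quality trends (hardening, q-value magnitudes), not a replacement
#' for a full spectrum code; measured spectra can be supplied via
#' \code{\link{readSpectrum}} instead.
#'
#' @param kvp tube voltage, kV; must exceed 10.
#' @param filtrationMmAl additional aluminium filtration thickness, mm.
#' @param filtrationMmCu additional copper filtration thickness, mm.
#' @param binWidthKev energy bin width, keV.
#' @param inherentMmAl inherent tube filtration in mm aluminium equivalent
#'   (window, oil, collimator); clinical tubes carry about 2.5 mm Al.
#' @return A \linkS4class{Spectrum} (relative fluence scale).
#' @export
makeSpectrum <- function(kvp, filtrationMmAl = 0, filtrationMmCu = 0,
                         binWidthKev = 1, inherentMmAl = 2.5) {
  if (kvp <= 10) stopf("validation error: kvp must exceed 10 keV")
  energies <- seq(10, kvp, by = binWidthKev)
  fl <- pmax((kvp - energies) / energies, 0)
  filtrationMmAl <- filtrationMmAl + inherentMmAl
  if (filtrationMmAl > 0) {
    tab <- .attenuationTable("Al")
    mu <- interpLogLog(tab$energy_keV, tab$mu_over_rho_cm2_per_g, energies)
    fl <- fl * exp(-mu * 2.699 * filtrationMmAl / 10)  # rho_Al, mm -> cm
  }
  if (filtrationMmCu > 0) {
    tab <- .attenuationTable("Cu")
    mu <- interpLogLog(tab$energy_keV, tab$mu_over_rho_cm2_per_g, energies)
    fl <- fl * exp(-mu * 8.96 * filtrationMmCu / 10)   # rho_Cu
  }
  Spectrum(energies, fl, binWidthKev)
}
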