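# Slanted-edge effective MTF estimation: per-row sub-pixel edge crossings
# -> edge angle -> super-sampled ESF (0.1 pixel-pitch bins) -> LSF by
# central difference (optional Hann window) -> Fourier modulus, normalised
# to 1 at zero frequency, averaged over the acquired edge images and
# rescaled to object-plane frequencies.

# Sub-pixel edge crossing per row: centroid of the gradient magnitude in a
# window around its maximum. Returns row/col (px) plus the failed rows.
.edgeCrossings <- function(px) {
  amp <- diff(range(px))
  nr <- nrow(px); nc <- ncol(px)
  rows <- integer(0); cols <- numeric(0); failed <- 0L
  for (r in seq_len(nr)) {
    g <- abs(diff(px[r, ]))
    gm <- max(g)
    if (amp <= 0 || gm < 0.05 * amp) { failed <- failed + 1L; next }
    j <- which.max(g)
    win <- max(1, j - 5):min(nc - 1, j + 5)
    pos <- win + 0.5                      # gradient sample positions
    w <- g[win]
    cols <- c(cols, sum(w * pos) / sum(w))
    rows <- c(rows, r)
  }
  list(rows = rows, cols = cols, failed = failed, total = nr)
}

#' Estimate the slanted-edge tilt angle
#'
#' Fits a least-squares line through the per-row sub-pixel edge crossings
#' (centroid of each row's gradient magnitude) and returns the tilt of the
#' edge from the vertical (column) axis in degrees.
#'
#' @param roi a \linkS4class{RadiographImage} (or bare matrix) containing
#'   exactly one edge transition per row.
#' @return angle in degrees, in (0, 45); a warning is raised below 0.5
#'   degrees, where super-sampling degenerates.
#' @export
estimateEdgeAngle <- function(roi) {
  px <- if (is(roi, "RadiographImage")) pixels(roi) else roi
  cr <- .edgeCrossings(px)
  if (cr$failed > 0.05 * cr$total)
    stopf("edge-detection error: no transition found in %d of %d rows",
          cr$failed, cr$total)
  fit <- stats::lm(cr$cols ~ cr$rows)
  slope <- abs(stats::coef(fit)[2])
  angle <- atan(slope) * 180 / pi
  if (angle >= 45)
    stopf("edge-detection error: estimated angle %.1f degrees out of range", angle)
  if (angle < 0.5)
    warning(sprintf("edge angle %.2f degrees < 0.5: super-sampling is degenerate",
                    angle))
  unname(angle)
}

#' Build the super-sampled edge spread function
#'
#' Assigns every ROI pixel its signed distance to the fitted edge line,
#' bins the distances at \code{esfBinFraction} of the pixel pitch and
#' averages the linearized pixel values per bin. Empty interior bins are
#' filled by linear interpolation (their count is recorded in
#' \code{binCounts} as 0).
#'
#' @param roi a linearized \linkS4class{RadiographImage}.
#' @param angleDeg optional edge angle override in degrees; estimated from
#'   the ROI when \code{NULL}.
#' @param config an \linkS4class{EdgeAnalysisConfig}.
#' @return An \linkS4class{EsfProfile}.
#' @export
buildEsf <- function(roi, angleDeg = NULL, config = EdgeAnalysisConfig()) {
  if (!isLinearized(roi))
    stopf("ROI must be linearized before ESF construction")
  px <- pixels(roi)
  pitch <- pixelPitch(roi)
  cr <- .edgeCrossings(px)
  if (cr$failed > 0.05 * cr$total)
    stopf("edge-detection error: no transition found in %d of %d rows",
          cr$failed, cr$total)
  if (is.null(angleDeg)) {
    fit <- stats::lm(cr$cols ~ cr$rows)
    slope <- stats::coef(fit)[2]
    intercept <- stats::coef(fit)[1]
  } else {
    slope <- sign(stats::coef(stats::lm(cr$cols ~ cr$rows))[2]) *
      tan(angleDeg * pi / 180)
    intercept <- mean(cr$cols - slope * cr$rows)
  }
  th <- atan(abs(slope))
  h <- config@esfBinFraction * pitch
  nr <- nrow(px); nc <- ncol(px)
  colIdx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rowIdx <- matrix(seq_len(nr), nr, nc)
  dMm <- (colIdx - intercept - slope * rowIdx) * cos(th) * pitch
  idx <- as.integer(round(dMm / h))
  shift <- 1L - min(idx)
  idx <- idx + shift
  nb <- max(idx)
  counts <- tabulate(idx, nbins = nb)
  sums <- as.vector(rowsum(as.vector(px), idx))
  # rowsum drops absent levels; rebuild dense vectors
  present <- sort(unique(idx))
  vals <- rep(NA_real_, nb)
  vals[present] <- sums / counts[present]
  interior <- seq(min(present), max(present))
  nEmpty <- sum(is.na(vals[interior]))
  if (nEmpty > 0.1 * length(interior))
    stopf("binning error: %d of %d interior ESF bins empty (angle too shallow for ROI)",
          nEmpty, length(interior))
  if (nEmpty > 0) {
    filled <- stats::approx(interior[!is.na(vals[interior])],
                            vals[interior][!is.na(vals[interior])],
                            xout = interior)$y
    vals[interior] <- filled
  }
  keep <- interior
  new("EsfProfile",
      positionsMm = (keep - shift) * h,
      values = vals[keep],
      binCounts = as.numeric(counts[keep]),
      binWidthMm = h)
}

#' Differentiate the ESF into the line spread function
#'
#' Central-difference derivative on the uniform super-sampled grid, with
#' an optional Hann window centered on the LSF peak and spanning the full
#' profile (the default for noisy measured data; oracle tests run with the
#' window off).
#'
#' @param esf an \linkS4class{EsfProfile}.
#' @param config an \linkS4class{EdgeAnalysisConfig}; its \code{window}
#'   field selects the taper.
#' @return list with \code{positionsMm}, \code{values} (the sampled LSF)
#'   and \code{binWidthMm}.
#' @export
esfToLsf <- function(esf, config = EdgeAnalysisConfig()) {
  v <- esf@values
  n <- length(v)
  if (n < 3) stopf("validation error: ESF profile shorter than 3 bins")
  h <- esf@binWidthMm
  lsf <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  pos <- esf@positionsMm[2:(n - 1)]
  if (config@window == "hann") {
    m <- length(lsf)
    ipeak <- which.max(abs(lsf))
    k <- seq_len(m) - ipeak
    w <- ifelse(abs(k) <= m / 2, cos(pi * k / m)^2, 0)
    lsf <- lsf * w
  }
  list(positionsMm = pos, values = lsf, binWidthMm = h)
}

#' Fourier modulus of the LSF, normalised at zero frequency
#'
#' Computes the modulus of the discrete Fourier transform of the sampled
#' LSF, divides by its zero-frequency value so the MTF is exactly 1 at
#' f = 0, and reports the curve on the uniform DFT grid up to
#' \code{maxFreq} (the detector Nyquist, when supplied). With
#' \code{compensate = TRUE}, the known transfer functions of the
#' super-sampling bin box and the central-difference kernel are divided
#' out.
#'
#' @param lsf list from \code{\link{esfToLsf}} (fields \code{values},
#'   \code{binWidthMm}).
#' @param superPitchMm super-sampled bin width, mm; defaults to
#'   \code{lsf$binWidthMm}.
#' @param maxFreq highest frequency to report, mm^-1; defaults to the
#'   super-sampled half-band.
#' @param compensate divide out the bin-box and finite-difference
#'   responses.
#' @return A detector-plane eMTF \linkS4class{FrequencySeries}.
#' @export
lsfToMtf <- function(lsf, superPitchMm = NULL, maxFreq = NULL,
                     compensate = FALSE) {
  v <- if (is.list(lsf)) lsf$values else as.numeric(lsf)
  h <- if (!is.null(superPitchMm)) superPitchMm
       else if (is.list(lsf)) lsf$binWidthMm
       else stopf("superPitchMm required when lsf is a bare vector")
  n <- length(v)
  mod <- Mod(stats::fft(v))
  if (mod[1] == 0)
    stopf("normalization error: zero-frequency component is 0")
  freqs <- (seq_len(n) - 1) / (n * h)
  if (is.null(maxFreq)) maxFreq <- 1 / (2 * h)
  keep <- which(freqs <= maxFreq + 1e-12)
  mtf <- mod[keep] / mod[1]
  if (compensate) {
    f <- freqs[keep]
    corr <- abs(sincx(pi * f * h)) * abs(sincx(2 * pi * f * h))
    mtf <- mtf / pmax(corr, 0.2)
  }
  FrequencySeries(freqs[keep], mtf, plane = "detector", quantity = "eMTF")
}

#' Average edge MTFs and project to the object plane
#'
#' Resamples the detector-plane MTF curves of the individual edge images
#' onto a common uniform grid (0.01 mm^-1 by default), takes the pointwise
#' mean and multiplies the frequencies by the geometric magnification
#' m = SID / (SID - object offset); m = 1 when the measured axis is the
#' unmagnified scan direction.
#'
#' @param curves list of detector-plane eMTF
#'   \linkS4class{FrequencySeries}.
#' @param geometry a \linkS4class{GeometrySetup}.
#' @param step common grid step before projection, mm^-1.
#' @return An object-plane eMTF \linkS4class{FrequencySeries}.
#' @export
averageAndProject <- function(curves, geometry, step = 0.01) {
  if (!length(curves)) stopf("no curves supplied")
  for (cv in curves) {
    if (plane(cv) != "detector")
      stopf("validation error: all curves must be detector-plane")
    if (quantity(cv) != "eMTF")
      stopf("validation error: all curves must be eMTF")
  }
  fmax <- min(vapply(curves, function(cv) max(frequencies(cv)), numeric(1)))
  grid <- seq(0, floor(fmax / step + 1e-9) * step, by = step)
  vals <- vapply(curves, function(cv)
    stats::approx(frequencies(cv), seriesValues(cv), xout = grid)$y,
    numeric(length(grid)))
  meanVals <- if (is.matrix(vals)) rowMeans(vals) else vals
  m <- magnification(geometry)
  FrequencySeries(grid * m, meanVals, plane = "object", quantity = "eMTF")
}

# Central square ROI of a given physical size.
extractCentralRoi <- function(image, roiSizeMm) {
  px <- pixels(image)
  n <- floor(roiSizeMm / pixelPitch(image))
  n <- min(n, nrow(px), ncol(px))
  r0 <- floor((nrow(px) - n) / 2)
  c0 <- floor((ncol(px) - n) / 2)
  RadiographImage(px[r0 + seq_len(n), c0 + seq_len(n)], pixelPitch(image),
                  linearized = isLinearized(image),
                  meta = acquisitionMeta(image))
}

#' Full slanted-edge eMTF pipeline
#'
#' For each linearized edge image: extract the central analysis ROI,
#' estimate the edge angle, build the super-sampled ESF, differentiate
#' (with the configured window), Fourier-transform and normalise; then
#' average the per-image curves and project the frequencies to the object
#' plane.
#'
#' @param edgeImages list of linearized edge
#'   \linkS4class{RadiographImage}s (nominally 5).
#' @param config an \linkS4class{EdgeAnalysisConfig}.
#' @param geometry a \linkS4class{GeometrySetup}.
#' @return An object-plane eMTF \linkS4class{FrequencySeries}.
#' @export
estimateEmtf <- function(edgeImages, config = EdgeAnalysisConfig(),
                         geometry = GeometrySetup(100)) {
  curves <- lapply(edgeImages, function(im) {
    roi <- extractCentralRoi(im, config@roiSizeMm)
    esf <- buildEsf(roi, angleDeg = NULL, config = config)
    lsf <- esfToLsf(esf, config)
    lsfToMtf(lsf, maxFreq = 1 / (2 * pixelPitch(im)),
             compensate = config@compensate)
  })
  averageAndProject(curves, geometry)
}
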