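# Beam-stop scatter fraction: the mean linearized signal inside disk ROIs
# behind the central 5x5 lead cylinders, divided by the mean background
# signal in equal-area ROIs at the midpoints between those cylinders.

# Mean pixel value inside a disk of radius radMm centered at (cyMm, cxMm)
# relative to the image center.
.diskMean <- function(px, pitch, cyMm, cxMm, radMm) {
  nr <- nrow(px); nc <- ncol(px)
  y <- (seq_len(nr) - (nr + 1) / 2) * pitch
  x <- (seq_len(nc) - (nc + 1) / 2) * pitch
  ri <- which(abs(y - cyMm) <= radMm)
  ci <- which(abs(x - cxMm) <= radMm)
  if (!length(ri) || !length(ci))
    stopf("geometry error: ROI at (%.1f, %.1f) mm falls outside the image",
          cyMm, cxMm)
  dd <- outer((y[ri] - cyMm)^2, (x[ci] - cxMm)^2, "+")
  sel <- dd <= radMm^2
  if (!any(sel))
    stopf("geometry error: ROI at (%.1f, %.1f) mm contains no pixels",
          cyMm, cxMm)
  mean(px[ri, ci][sel])
}

# Label connected runs of a logical mask (8-connectivity via row-run
# merging with union-find); returns centroids and areas.
.labelMask <- function(mask, pitch) {
  nr <- nrow(mask); nc <- ncol(mask)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  runs <- list()   # per row: list of (start, end, label)
  prev <- NULL
  for (r in seq_len(nr)) {
    m <- mask[r, ]
    rl <- rle(m)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    cur <- list()
    for (k in which(rl$values)) {
      parent <- c(parent, 0L)
      lab <- length(parent)
      parent[lab] <- lab
      s <- starts[k]; e <- ends[k]
      if (!is.null(prev)) for (p in prev) {
        if (p$s <= e + 1 && p$e >= s - 1) {   # touching or overlapping
          ra <- find(p$lab); rb <- find(lab)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
      cur[[length(cur) + 1]] <- list(s = s, e = e, lab = lab, row = r)
      runs[[length(runs) + 1]] <- list(s = s, e = e, lab = lab, row = r)
    }
    prev <- cur
  }
  if (!length(runs)) return(NULL)
  roots <- vapply(seq_along(parent), find, integer(1))
  labOf <- match(roots, sort(unique(roots)))
  nLab <- max(labOf)
  area <- numeric(nLab); sy <- numeric(nLab); sx <- numeric(nLab)
  for (rn in runs) {
    l <- labOf[rn$lab]
    w <- rn$e - rn$s + 1
    area[l] <- area[l] + w
    sy[l] <- sy[l] + rn$row * w
    sx[l] <- sx[l] + sum(rn$s:rn$e)
  }
  cy <- (sy / area - (nr + 1) / 2) * pitch
  cx <- (sx / area - (nc + 1) / 2) * pitch
  data.frame(cyMm = cy, cxMm = cx, areaPx = area)
}

# Detect the beam-stop grid from the image: threshold at half the
# background level, label the shadows, reconstruct the grid spec.
.autoDetectGrid <- function(px, pitch, expectedRows = 11, expectedCols = 11) {
  background <- stats::median(px)
  mask <- px < 0.5 * background
  comps <- .labelMask(mask, pitch)
  if (is.null(comps)) stopf("detection error: found 0 cylinder shadows")
  comps <- comps[comps$areaPx >= 4, , drop = FALSE]
  nExp <- expectedRows * expectedCols
  if (nrow(comps) != nExp)
    stopf("detection error: found %d cylinder shadows, expected %d",
          nrow(comps), nExp)
  rowPos <- sort(comps$cyMm)
  rowCenters <- colMeans(matrix(rowPos, nrow = expectedCols))
  colPos <- sort(comps$cxMm)
  colCenters <- colMeans(matrix(colPos, nrow = expectedRows))
  pitchEst <- mean(c(diff(rowCenters), diff(colCenters)))
  diamEst <- 2 * sqrt(stats::median(comps$areaPx) / pi) * pitch
  BeamStopGridSpec(expectedRows, expectedCols, pitchEst, diamEst,
                   centerOffsetMm = c(mean(rowCenters), mean(colCenters)))
}

#' Measure the scatter fraction from a beam-stop image
#'
#' Samples a disk ROI of 60 percent of the cylinder diameter at each of
#' the central 5x5 cylinder positions (the attenuated signal) and
#' equal-area disk ROIs at the horizontal and vertical midpoints between
#' those cylinders (the background), and returns their ratio: the scatter
#' fraction.
#'
#' @param image a linearized beam-stop \linkS4class{RadiographImage}.
#' @param grid a \linkS4class{BeamStopGridSpec}, or \code{"auto"} to
#'   detect the grid by thresholding at half the background level and
#'   centroid clustering.
#' @param expectedRows,expectedCols grid dimensions assumed by auto
#'   detection.
#' @return A \linkS4class{ScatterResult}.
#' @examples
#' g <- BeamStopGridSpec(11, 11, pitchMm = 12, cylinderDiameterMm = 3)
#' bs <- makeBeamStopImage(g, primaryLevel = 700, scatterLevel = 300,
#'                         pitchMm = 0.25, shape = c(600, 600), seed = 2)
#' scatterFraction(measureScatterFraction(bs$image, g))  # ~0.30
#' @export
measureScatterFraction <- function(image, grid = "auto",
                                   expectedRows = 11, expectedCols = 11) {
  px <- pixels(image)
  pitch <- pixelPitch(image)
  if (identical(grid, "auto"))
    grid <- .autoDetectGrid(px, pitch, expectedRows, expectedCols)
  validObject(grid)
  roiRad <- 0.6 * grid@cylinderDiameterMm / 2
  if (grid@pitchMm / 2 <= grid@cylinderDiameterMm / 2 + roiRad)
    stopf("geometry error: background ROI would overlap a cylinder shadow")
  # central 5x5 block of cylinder centers
  rSel <- seq(floor((grid@nRows - 5) / 2) + 1, length.out = 5)
  cSel <- seq(floor((grid@nCols - 5) / 2) + 1, length.out = 5)
  ro <- ((rSel) - (grid@nRows + 1) / 2) * grid@pitchMm + grid@centerOffsetMm[1]
  co <- ((cSel) - (grid@nCols + 1) / 2) * grid@pitchMm + grid@centerOffsetMm[2]
  leadVals <- as.vector(vapply(co, function(cx)
    vapply(ro, function(cy) .diskMean(px, pitch, cy, cx, roiRad),
           numeric(1)), numeric(length(ro))))
  # background: 4-neighbour midpoints between adjacent sampled cylinders
  half <- grid@pitchMm / 2
  bgH <- expand.grid(cy = ro, cx = co[-length(co)] + half)
  bgV <- expand.grid(cy = ro[-length(ro)] + half, cx = co)
  bg <- rbind(bgH, bgV)
  bgVals <- mapply(function(cy, cx) .diskMean(px, pitch, cy, cx, roiRad),
                   bg$cy, bg$cx)
  mpvLead <- mean(leadVals)
  mpvBg <- mean(bgVals)
  if (mpvBg <= 0) stopf("background signal is non-positive")
  sf <- mpvLead / mpvBg
  if (sf >= 1)
    stopf("measured SF %.3f >= 1: attenuated signal exceeds background", sf)
  new("ScatterResult", sf = sf, mpvLead = mpvLead, mpvBackground = mpvBg,
      nCylindersUsed = 25)
}
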