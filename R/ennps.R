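# Effective normalised noise power spectrum from flat-field images:
# overlapping square sub-ROIs of a central analysis ROI, per-sub-ROI
# detrending, averaged squared Fourier modulus, normalised by the squared
# mean linearized signal. The 1D curve averages the 2D spectrum over a
# band of columns flanking the vertical frequency axis, excluding the
# on-axis column.

#' Extract overlapping sub-ROIs from a flat field
#'
#' Tiles the central \code{roiPx} x \code{roiPx} window with square
#' sub-ROIs of side \code{subPx}, overlapping by \code{overlapPx} in both
#' directions; at the defaults (1024 / 256 / 128) this yields
#' ((1024-256)/128 + 1)^2 = 49 sub-ROIs per image.
#'
#' @param image a linearized \linkS4class{RadiographImage}.
#' @param config an \linkS4class{NnpsConfig}.
#' @return list of numeric sub-ROI matrices.
#' @export
extractSubrois <- function(image, config = NnpsConfig()) {
  px <- pixels(image)
  roi <- config@roiPx; sub <- config@subPx
  step <- sub - config@overlapPx
  if (nrow(px) < roi || ncol(px) < roi)
    stopf("size error: image %d x %d smaller than the %d px ROI; use a scaled-down NnpsConfig",
          nrow(px), ncol(px), roi)
  r0 <- floor((nrow(px) - roi) / 2)
  c0 <- floor((ncol(px) - roi) / 2)
  starts <- seq(1, roi - sub + 1, by = step)
  out <- vector("list", length(starts)^2)
  k <- 0
  for (i in starts) for (j in starts) {
    k <- k + 1
    out[[k]] <- px[r0 + i - 1 + seq_len(sub), c0 + j - 1 + seq_len(sub)]
  }
  out
}

# Orthonormal basis of the 2D quadratic surface on an n x n grid.
.poly2dBasis <- function(n) {
  x <- rep((seq_len(n) - (n + 1) / 2) / (n / 2), times = n)  # rows vary fast
  y <- rep((seq_len(n) - (n + 1) / 2) / (n / 2), each = n)
  X <- cbind(1, x, y, x^2, x * y, y^2)
  qr.Q(qr(X))
}

#' Two-dimensional effective NNPS
#'
#' Detrends every sub-ROI (2D quadratic surface subtracted by default, a
#' plain mean as fallback), computes
#' \eqn{NPS(u,v) = \frac{\Delta x \Delta y}{N_x N_y}\,
#' \langle |DFT_2(residual)|^2 \rangle} over all sub-ROIs of all images,
#' and normalises by the squared mean linearized signal of the analysis
#' ROIs to give NNPS in mm^2, on frequency axes symmetric about zero.
#'
#' @param images list of linearized flat-field
#'   \linkS4class{RadiographImage}s with equal pitch and comparable means
#'   (a warning is raised beyond 10 percent spread).
#' @param config an \linkS4class{NnpsConfig}.
#' @return An \linkS4class{Nnps2D}.
#' @export
nnps2d <- function(images, config = NnpsConfig()) {
  if (!length(images)) stopf("no images supplied")
  pitches <- vapply(images, pixelPitch, numeric(1))
  if (max(pitches) - min(pitches) > 1e-9)
    stopf("all images must share a pixel pitch")
  for (im in images) if (!isLinearized(im))
    stopf("flat fields must be linearized before NNPS estimation")
  pitch <- pitches[1]
  n <- config@subPx
  Q <- if (config@detrend == "poly2d") .poly2dBasis(n) else NULL
  acc <- matrix(0, n, n)
  nSub <- 0L
  roiMeans <- numeric(length(images))
  for (ii in seq_along(images)) {
    subs <- extractSubrois(images[[ii]], config)
    roiMeans[ii] <- mean(vapply(subs, mean, numeric(1)))
    for (s in subs) {
      z <- as.vector(s)
      resid <- if (is.null(Q)) z - mean(z)
               else z - Q %*% crossprod(Q, z)
      acc <- acc + Mod(stats::fft(matrix(resid, n, n)))^2
      nSub <- nSub + 1L
    }
  }
  if (nSub < 2) stopf("estimation error: fewer than 2 sub-ROIs in total")
  if (max(roiMeans) > 1.1 * min(roiMeans))
    warning("flat-field means differ by more than 10%; NNPS may be biased")
  meanSignal <- mean(roiMeans)
  nps <- (pitch^2 / (n * n)) * acc / nSub
  nnps <- nps / meanSignal^2
  # fftshift both axes so frequency 0 sits at index n/2 + 1
  half <- n %/% 2
  ord <- c((half + 1):n, 1:half)
  nnps <- nnps[ord, ord]
  freqs <- (seq_len(n) - half - 1) / (n * pitch)
  new("Nnps2D", u = freqs, v = freqs, nnps = nnps,
      nSubrois = as.numeric(nSub), meanSignal = meanSignal,
      pixelPitchMm = pitch)
}

#' One-dimensional vertical eNNPS
#'
#' Averages the 2D NNPS over a band of \code{bandLines} frequency columns
#' on each side of the vertical frequency axis (excluding the on-axis
#' column itself when \code{excludeAxis}), folds negative vertical
#' frequencies onto positive ones, and rescales the frequencies to the
#' object plane with the same magnification convention as the eMTF.
#'
#' @param n2 an \linkS4class{Nnps2D}.
#' @param config an \linkS4class{NnpsConfig}.
#' @param geometry optional \linkS4class{GeometrySetup}; when supplied the
#'   curve is object-plane, otherwise detector-plane.
#' @return An eNNPS \linkS4class{FrequencySeries} (mm^2).
#' @export
nnps1dVertical <- function(n2, config = NnpsConfig(), geometry = NULL) {
  n <- length(n2@v)
  half <- n %/% 2
  center <- half + 1L
  band <- config@bandLines
  if (band > half - 1)
    stopf("validation error: band of %d lines wider than the frequency grid", band)
  offs <- c(-(band:1), if (config@excludeAxis) NULL else 0L, 1:band)
  colsSel <- center + offs
  prof <- rowMeans(n2@nnps[, colsSel, drop = FALSE])
  # fold to non-negative vertical frequencies
  ks <- 0:(half - 1)
  folded <- vapply(ks, function(k) {
    if (k == 0) prof[center]
    else mean(c(prof[center + k], prof[center - k]))
  }, numeric(1))
  freqs <- ks / (n * n2@pixelPitchMm)
  m <- if (is.null(geometry)) 1 else magnification(geometry)
  FrequencySeries(freqs * m, folded,
                  plane = if (is.null(geometry)) "detector" else "object",
                  quantity = "eNNPS")
}
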