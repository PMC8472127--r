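#' Resample curves onto a common frequency grid
#'
#' Deterministic curves (eMTF, eDQE, eNEQ) are linearly interpolated onto
#' \{0, step, ..., fmax\}. Noise power curves (quantity \code{"eNNPS"})
#' are instead bin-averaged: the value at each reporting frequency is the
#' mean of the native-grid estimates falling within half a step of it,
#' the standard way noise power spectra are reported on a coarse grid
#' (each native bin is a noisy periodogram estimate, so averaging the
#' bins inside a reporting cell is both the conventional reduction and a
#' variance cut; interpolation would keep single-bin noise). No
#' extrapolation -- every curve must cover the requested range.
#'
#' @param curves list of \linkS4class{FrequencySeries}.
#' @param step grid step, mm^-1 (0.1 default, the reporting grid of the
#'   statistics stage).
#' @param fmax highest grid frequency, mm^-1; defaults to the largest
#'   multiple of \code{step} covered by every curve.
#' @return list of \linkS4class{FrequencySeries} on the shared grid.
#' @export
resampleCommonGrid <- function(curves, step = 0.1, fmax = NULL) {
  supports <- vapply(curves, function(cv) max(frequencies(cv)), numeric(1))
  if (is.null(fmax)) fmax <- floor(min(supports) / step + 1e-9) * step
  bad <- which(supports < fmax - 1e-9)
  if (length(bad))
    stopf("range error: curve %d (%s) covers only up to %.3g mm^-1 < fmax %.3g",
          bad[1], quantity(curves[[bad[1]]]), supports[bad[1]], fmax)
  grid <- seq(0, fmax, by = step)
  lapply(curves, function(cv) {
    f <- frequencies(cv)
    y <- seriesValues(cv)
    v <- if (quantity(cv) == "eNNPS") {
      vapply(grid, function(g) {
        inCell <- which(abs(f - g) <= step / 2 + 1e-12)
        if (length(inCell)) mean(y[inCell])
        else stats::approx(f, y, xout = g)$y
      }, numeric(1))
    } else {
      stats::approx(f, y, xout = grid)$y
    }
    FrequencySeries(grid, v, plane = plane(cv), quantity = quantity(cv))
  })
}

#' Effective noise equivalent quanta
#'
#' \deqn{eNEQ(f) = \frac{eMTF(f)^2 (1 - SF)^2}{eNNPS(f)}}
#' in mm^-2, on the measurement's common object-plane grid. Grid points
#' with non-positive eNNPS are masked (NA) with a warning; more than 20
#' percent masked is an error.
#'
#' @param m a \linkS4class{SystemMeasurement}.
#' @return An eNEQ \linkS4class{FrequencySeries}.
#' @export
eneq <- function(m) {
  validObject(m)
  mtf <- seriesValues(m@emtf)
  nnps <- seriesValues(m@ennps)
  bad <- !(nnps > 0)
  if (sum(bad) > 0.2 * length(nnps))
    stopf("more than 20%% of eNNPS grid points are non-positive")
  if (any(bad))
    warning(sprintf("masking %d grid points with non-positive eNNPS", sum(bad)))
  v <- mtf^2 * (1 - m@sf)^2 / nnps
  v[bad] <- NA_real_
  FrequencySeries(frequencies(m@emtf), v, plane = plane(m@emtf),
                  quantity = "eNEQ")
}

#' Effective detective quantum efficiency
#'
#' \deqn{eDQE(f) = \frac{eMTF(f)^2 (1 - SF)^2}{eNNPS(f)\, TF\, AK\, q}}
#' equivalently \eqn{eNEQ(f) / (TF \cdot AK \cdot q)}, dimensionless.
#' AK is the phantom-free air kerma corrected to the detector plane.
#'
#' @param m a \linkS4class{SystemMeasurement}.
#' @return An eDQE \linkS4class{FrequencySeries}.
#' @export
edqe <- function(m) {
  denom <- m@tf * m@akUGy * m@qPerUGyMm2
  if (!(denom > 0)) stopf("validation error: TF * AK * q must be positive")
  nq <- eneq(m)
  FrequencySeries(frequencies(nq), seriesValues(nq) / denom,
                  plane = plane(nq), quantity = "eDQE")
}

#' Peak of a metric curve
#'
#' Maximum value over the reported grid and the frequency at which it is
#' attained; ties resolve to the lowest frequency.
#'
#' @param curve a \linkS4class{FrequencySeries}.
#' @return named numeric c(frequency, value).
#' @export
maxPeak <- function(curve) {
  v <- seriesValues(curve)
  ok <- which(!is.na(v))
  if (!length(ok)) stopf("validation error: curve has no usable values")
  i <- ok[which.max(v[ok])]
  c(frequency = frequencies(curve)[i], value = v[i])
}
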