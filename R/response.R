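#' Fit the detector response function
#'
#' Least-squares fit of mean pixel value (MPV) against detector air kerma,
#' as a straight line (flat-panel detectors) or a fifth-order polynomial
#' (detectors with a non-linear response). The fitted model must be
#' strictly monotone increasing over the fitted kerma range; a
#' non-monotone fit is rejected with the location of the turning point
#' rather than silently constrained.
#'
#' @param dakUGy detector air kerma values, uGy; distinct.
#' @param mpv mean pixel values, same length.
#' @param kind \code{"linear"} (>= 2 points) or \code{"polynomial5"}
#'   (>= 6 points).
#' @return A \linkS4class{ResponseModel} with the coefficient of
#'   determination of the fit.
#' @examples
#' m <- fitResponse(1:10, 2 * (1:10) + 5, "linear")
#' coef(m)       # c(5, 2)
#' m@rSquared    # 1
#' @export
fitResponse <- function(dakUGy, mpv, kind = c("linear", "polynomial5")) {
  kind <- match.arg(kind)
  if (length(dakUGy) != length(mpv))
    stopf("dakUGy and mpv must have the same length")
  if (anyDuplicated(dakUGy))
    stopf("validation error: dak values must be distinct")
  degree <- if (kind == "linear") 1L else 5L
  if (length(dakUGy) < degree + 1)
    stopf("validation error: %s fit needs at least %d samples, got %d",
          kind, degree + 1, length(dakUGy))
  fit <- stats::lm(mpv ~ stats::poly(dakUGy, degree, raw = TRUE))
  coeffs <- as.numeric(stats::coef(fit))
  coeffs[is.na(coeffs)] <- 0
  rng <- range(dakUGy)
  grid <- seq(rng[1], rng[2], length.out = 1000)
  deriv <- .polyEval(coeffs[-1] * seq_len(degree), grid)
  if (any(deriv <= 0)) {
    turn <- grid[which(deriv <= 0)[1]]
    stopf("monotonicity error: fitted response turns at about %.4g uGy", turn)
  }
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((mpv - mean(mpv))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  new("ResponseModel", kind = kind, coefficients = coeffs,
      validRangeUGy = rng, rSquared = r2)
}

#' Coefficients of a fitted response model
#'
#' @param object a \linkS4class{ResponseModel}.
#' @param ... ignored.
#' @return numeric coefficients, intercept first.
#' @export
setMethod("coef", "ResponseModel", function(object, ...) object@coefficients)

#' Evaluate the forward response model
#'
#' @param model a \linkS4class{ResponseModel}.
#' @param dakUGy kerma values, uGy.
#' @return predicted mean pixel values.
#' @export
predictResponse <- function(model, dakUGy) {
  .polyEval(model@coefficients, dakUGy)
}

#' Linearize an image through a fitted response model
#'
#' Maps every pixel through the inverse of the fitted response to
#' kerma-proportional units (uGy). The inverse is computed by monotone
#' piecewise-cubic interpolation of 1000 forward samples over the model's
#' fitted kerma range, which works identically for the linear and
#' fifth-order kinds. Pixels outside the invertible output range are
#' clamped (with a reported count); more than 1 percent clamped is an
#' error.
#'
#' @param image a raw \linkS4class{RadiographImage}.
#' @param model a \linkS4class{ResponseModel}.
#' @return the linearized \linkS4class{RadiographImage}.
#' @examples
#' m <- fitResponse(1:10, 2 * (1:10) + 5, "linear")
#' img <- RadiographImage(matrix(25, 4, 4), 0.143)
#' mean(pixels(linearize(img, m)))  # 10 uGy
#' @export
linearize <- function(image, model) {
  if (isLinearized(image))
    stopf("image is already linearized")
  kGrid <- seq(model@validRangeUGy[1], model@validRangeUGy[2],
               length.out = 1000)
  yGrid <- predictResponse(model, kGrid)
  inv <- stats::splinefun(yGrid, kGrid, method = "hyman")
  px <- pixels(image)
  low <- px < yGrid[1]
  high <- px > yGrid[length(yGrid)]
  nClamped <- sum(low) + sum(high)
  if (nClamped > 0.01 * length(px))
    stopf("linearization error: %d of %d pixels (%.1f%%) outside the invertible range",
          nClamped, length(px), 100 * nClamped / length(px))
  if (nClamped > 0)
    message(sprintf("linearize: clamped %d pixels to the invertible range",
                    nClamped))
  px[low] <- yGrid[1]
  px[high] <- yGrid[length(yGrid)]
  out <- inv(px)
  RadiographImage(matrix(pmax(out, 0), nrow(px), ncol(px)),
                  pixelPitch(image), linearized = TRUE,
                  meta = acquisitionMeta(image))
}

#' Fit a response model from an exposure series of images
#'
#' Convenience wrapper: computes the mean pixel value of every image and
#' fits \code{\link{fitResponse}} against the supplied kerma levels.
#'
#' @param images list of \linkS4class{RadiographImage}.
#' @param dakUGy kerma level per image, uGy.
#' @param kind passed to \code{\link{fitResponse}}.
#' @return A \linkS4class{ResponseModel}.
#' @export
fitResponseFromImages <- function(images, dakUGy,
                                  kind = c("linear", "polynomial5")) {
  mpv <- vapply(images, function(im) mean(pixels(im)), numeric(1))
  fitResponse(dakUGy, mpv, match.arg(kind))
}

#' Serialize a response model to JSON
#'
#' @param model a \linkS4class{ResponseModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResponseModel <- function(model, path) {
  jsonlite::write_json(
    list(kind = model@kind, coefficients = model@coefficients,
         valid_range_uGy = model@validRangeUGy, r_squared = model@rSquared),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a response model from JSON
#'
#' @param path JSON written by \code{\link{writeResponseModel}}.
#' @return A \linkS4class{ResponseModel}.
#' @export
readResponseModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ResponseModel", kind = x$kind, coefficients = as.numeric(x$coefficients),
      validRangeUGy = as.numeric(x$valid_range_uGy),
      rSquared = as.numeric(x$r_squared))
}
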