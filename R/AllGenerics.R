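#' Pixel matrix of an image
#' @param x a \linkS4class{RadiographImage}.
#' @return numeric matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Pixel pitch in mm
#' @param x a \linkS4class{RadiographImage} or \linkS4class{Nnps2D}.
#' @return numeric scalar, mm.
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' Is the image linearized?
#' @param x a \linkS4class{RadiographImage}.
#' @return logical scalar.
#' @export
setGeneric("isLinearized", function(x) standardGeneric("isLinearized"))

#' Acquisition metadata
#' @param x an object carrying an \linkS4class{AcquisitionMeta}.
#' @return an \linkS4class{AcquisitionMeta}.
#' @export
setGeneric("acquisitionMeta", function(x) standardGeneric("acquisitionMeta"))

#' Frequency grid of a curve
#' @param x a \linkS4class{FrequencySeries}.
#' @return numeric vector, mm^-1.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' Values of a curve
#' @param x a \linkS4class{FrequencySeries}.
#' @return numeric vector.
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' Reference plane of a curve
#' @param x a \linkS4class{FrequencySeries}.
#' @return \code{"detector"} or \code{"object"}.
#' @export
setGeneric("plane", function(x) standardGeneric("plane"))

#' Quantity tag of a curve
#' @param x a \linkS4class{FrequencySeries}.
#' @return character scalar.
#' @export
setGeneric("quantity", function(x) standardGeneric("quantity"))

#' Scatter fraction of a measurement
#' @param x a \linkS4class{ScatterResult} or \linkS4class{SystemMeasurement}.
#' @return numeric scalar in [0, 1).
#' @export
setGeneric("scatterFraction", function(x) standardGeneric("scatterFraction"))
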