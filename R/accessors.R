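#' @describeIn pixels pixel matrix of a radiograph
#' @export
setMethod("pixels", "RadiographImage", function(x) x@pixels)

#' @describeIn pixelPitch pitch of a radiograph
#' @export
setMethod("pixelPitch", "RadiographImage", function(x) x@pixelPitchMm)

#' @describeIn pixelPitch pitch behind an NNPS estimate
#' @export
setMethod("pixelPitch", "Nnps2D", function(x) x@pixelPitchMm)

#' @describeIn isLinearized linearization flag of a radiograph
#' @export
setMethod("isLinearized", "RadiographImage", function(x) x@linearized)

#' @describeIn acquisitionMeta metadata of a radiograph
#' @export
setMethod("acquisitionMeta", "RadiographImage", function(x) x@meta)

#' @describeIn acquisitionMeta metadata of a measurement bundle
#' @export
setMethod("acquisitionMeta", "SystemMeasurement", function(x) x@meta)

#' @describeIn frequencies grid of a frequency series
#' @export
setMethod("frequencies", "FrequencySeries", function(x) x@frequencies)

#' @describeIn seriesValues values of a frequency series
#' @export
setMethod("seriesValues", "FrequencySeries", function(x) x@values)

#' @describeIn plane plane of a frequency series
#' @export
setMethod("plane", "FrequencySeries", function(x) x@plane)

#' @describeIn quantity tag of a frequency series
#' @export
setMethod("quantity", "FrequencySeries", function(x) x@quantity)

#' @describeIn scatterFraction scatter fraction of a beam-stop result
#' @export
setMethod("scatterFraction", "ScatterResult", function(x) x@sf)

#' @describeIn scatterFraction scatter fraction of a measurement bundle
#' @export
setMethod("scatterFraction", "SystemMeasurement", function(x) x@sf)

setMethod("show", "RadiographImage", function(object) {
  cat(sprintf(
    "RadiographImage: %d x %d px, pitch %.4g mm, %s\n  system '%s'%s\n",
    nrow(object@pixels), ncol(object@pixels), object@pixelPitchMm,
    if (object@linearized) "linearized (kerma-proportional)" else "raw",
    object@meta@systemId,
    if (nzchar(object@meta@protocol))
      paste0(", protocol ", object@meta@protocol) else ""))
  invisible(object)
})

setMethod("show", "FrequencySeries", function(object) {
  f <- object@frequencies
  cat(sprintf(
    "FrequencySeries (%s, %s plane): %d samples, f = [%.3g, %.3g] mm^-1, step %.3g\n",
    object@quantity, object@plane, length(f), f[1], f[length(f)],
    f[2] - f[1]))
  invisible(object)
})

setMethod("show", "ResponseModel", function(object) {
  cat(sprintf(
    "ResponseModel (%s): MPV(K) over K in [%.4g, %.4g] uGy, R^2 = %.4f\n",
    object@kind, object@validRangeUGy[1], object@validRangeUGy[2],
    object@rSquared))
  cat("  coefficients (intercept first):",
      paste(signif(object@coefficients, 6), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "ScatterResult", function(object) {
  cat(sprintf(
    "ScatterResult: SF = %.4f (lead MPV %.4g / background MPV %.4g, %d cylinders)\n",
    object@sf, object@mpvLead, object@mpvBackground, object@nCylindersUsed))
  invisible(object)
})

setMethod("show", "SystemMeasurement", function(object) {
  cat(sprintf(
    "SystemMeasurement '%s': SF %.3f, TF %.3f, AK %.4g uGy, q %.4g mm^-2 uGy^-1\n",
    object@meta@systemId, object@sf, object@tf, object@akUGy,
    object@qPerUGyMm2))
  cat(sprintf("  grid: %d points on [%.3g, %.3g] mm^-1 (%s plane)\n",
              length(object@emtf@frequencies),
              min(object@emtf@frequencies), max(object@emtf@frequencies),
              object@emtf@plane))
  invisible(object)
})

setMethod("show", "Nnps2D", function(object) {
  cat(sprintf(
    "Nnps2D: %d x %d grid, %d sub-ROIs, mean signal %.4g, pitch %.4g mm\n",
    nrow(object@nnps), ncol(object@nnps), object@nSubrois,
    object@meanSignal, object@pixelPitchMm))
  invisible(object)
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport (%s), alpha = %.2f\n", object@metric,
              object@alpha))
  cat("Kruskal-Wallis per frequency bin:\n")
  print(object@kruskal, row.names = FALSE)
  if (nrow(object@pairwise)) {
    cat("Pairwise Mann-Whitney (hierarchical, unadjusted):\n")
    print(object@pairwise, row.names = FALSE)
  } else {
    cat("Pairwise tests suppressed (global test not significant).\n")
  }
  cat("Note: adjacent frequency samples are correlated; tests are exploratory.\n")
  invisible(object)
})
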