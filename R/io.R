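#' Read a radiographic image from disk
#'
#' Loads a raw "for-processing" radiograph from a 16-bit grayscale TIFF or
#' an uncompressed explicit-VR DICOM file. Pixel values are loaded
#' unmodified (a DICOM rescale slope/intercept, when the header mandates
#' one, is applied and reported); the returned image is flagged as not
#' linearized -- detector-response inversion is a separate, explicit step
#' (\code{\link{linearize}}).
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"tiff"} or
#'   \code{"dicom"}.
#' @param pixelPitchMm pitch override in mm. Mandatory for TIFF (which
#'   carries no trustworthy pitch) and for DICOM files without
#'   PixelSpacing.
#' @param meta optional \linkS4class{AcquisitionMeta} to attach.
#' @return A \linkS4class{RadiographImage}.
#' @examples
#' img <- makeFlatField(1000, 0, 0.143, c(16, 16), seed = 1)$image
#' f <- tempfile(fileext = ".tif")
#' writeImage(img, f)
#' rt <- readImage(f, pixelPitchMm = 0.143)
#' stopifnot(identical(pixels(rt), pixels(img)))
#' @export
readImage <- function(path, format = c("auto", "tiff", "dicom"),
                      pixelPitchMm = NULL, meta = AcquisitionMeta()) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff"
      else if (ext %in% c("dcm", "dicom")) "dicom"
      else stopf("cannot infer format of '%s'; pass format=", path)
  }
  if (format == "dicom")
    return(readDicom(path, pixelPitchMm = pixelPitchMm, meta = meta))
  if (is.null(pixelPitchMm))
    stopf("configuration error: pixelPitchMm override is required for TIFF input")
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3) px <- px[, , 1]
  storage.mode(px) <- "double"
  RadiographImage(px, pixelPitchMm, linearized = FALSE, meta = meta)
}

#' Write a radiographic image to disk
#'
#' Writes the pixel matrix as 16-bit grayscale TIFF or minimal DICOM
#' (see \code{\link{writeDicom}}). Values are rounded to integers; they
#' must lie in [0, 65535].
#'
#' @param image a \linkS4class{RadiographImage}.
#' @param path output path.
#' @param format \code{"auto"} (by extension), \code{"tiff"} or
#'   \code{"dicom"}.
#' @return \code{path}, invisibly.
#' @export
writeImage <- function(image, path, format = c("auto", "tiff", "dicom")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff"
      else if (ext %in% c("dcm", "dicom")) "dicom"
      else stopf("cannot infer format of '%s'; pass format=", path)
  }
  if (format == "dicom") return(writeDicom(image, path))
  px <- round(pixels(image))
  if (any(px < 0 | px > 65535))
    stopf("pixel values outside [0, 65535] cannot be written as 16-bit TIFF")
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a frequency series as CSV
#'
#' Columns: \code{frequency_mm^-1}, \code{value}, \code{plane},
#' \code{quantity}. Numbers are written with enough digits to round-trip
#' beyond 12 significant digits.
#'
#' @param series a \linkS4class{FrequencySeries}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSeries <- function(series, path) {
  validObject(series)
  df <- data.frame(
    `frequency_mm^-1` = sprintf("%.15g", frequencies(series)),
    value = sprintf("%.15g", seriesValues(series)),
    plane = plane(series),
    quantity = quantity(series),
    check.names = FALSE
  )
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stopf("cannot write series to '%s': %s", path,
                              conditionMessage(e))
  )
  invisible(path)
}

#' Read a frequency series from CSV
#'
#' Inverse of \code{\link{writeSeries}}.
#'
#' @param path CSV path.
#' @return A \linkS4class{FrequencySeries}.
#' @export
readSeries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  FrequencySeries(as.numeric(df[["frequency_mm^-1"]]),
                  as.numeric(df[["value"]]),
                  plane = as.character(df[["plane"]][1]),
                  quantity = as.character(df[["quantity"]][1]))
}

#' Write a spectrum as two-column CSV
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  df <- data.frame(energy_keV = sprintf("%.15g", spectrum@energiesKev),
                   fluence_per_mm2 = sprintf("%.15g", spectrum@fluencePerMm2))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from two-column CSV
#'
#' @param path CSV with columns \code{energy_keV}, \code{fluence_per_mm2}.
#' @return A \linkS4class{Spectrum}.
#' @export
readSpectrum <- function(path) {
  df <- utils::read.csv(path)
  Spectrum(as.numeric(df$energy_keV), as.numeric(df$fluence_per_mm2))
}

#' Load a protocol configuration file
#'
#' Reads a YAML protocol configuration (one file per system/protocol;
#' shipped examples replicate the study's chest and knee exposure
#' settings) and validates it into acquisition metadata plus measurement
#' geometry. Distances appear in cm in the file. Mandatory keys:
#' \code{system_id}, \code{protocol}, \code{tube_voltage_kV},
#' \code{sid_cm}, \code{sdd_cm}, \code{beam_mode}, \code{pixel_pitch_mm}
#' (the pitch has no default on purpose: it is detector-specific and not
#' always documented by vendors).
#'
#' @param path YAML file path.
#' @return A list with elements \code{meta}
#'   (\linkS4class{AcquisitionMeta}), \code{geometry}
#'   (\linkS4class{GeometrySetup}) and \code{pixelPitchMm}.
#' @examples
#' cfg <- system.file("extdata", "configs", "dr2_chest.yaml",
#'                    package = "effiq")
#' pc <- loadProtocolConfig(cfg)
#' pc$meta@tubeVoltageKv  # 145
#' @export
loadProtocolConfig <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  cfg <- yaml::read_yaml(path)
  mandatory <- c("system_id", "protocol", "tube_voltage_kV", "sid_cm",
                 "sdd_cm", "beam_mode", "pixel_pitch_mm")
  missing <- setdiff(mandatory, names(cfg))
  if (length(missing))
    stopf("configuration error: missing mandatory key '%s'", missing[1])
  if (cfg$sdd_cm > cfg$sid_cm)
    stopf("validation error: sdd_cm (%g) exceeds sid_cm (%g)",
          cfg$sdd_cm, cfg$sid_cm)
  meta <- AcquisitionMeta(
    systemId = cfg$system_id, protocol = cfg$protocol,
    tubeVoltageKv = cfg$tube_voltage_kV,
    tubeLoadMas = if (is.null(cfg$tube_load_mAs)) NA_real_ else cfg$tube_load_mAs,
    scanSpeed = if (is.null(cfg$scan_speed)) NA_real_ else cfg$scan_speed,
    sidCm = cfg$sid_cm,
    filtration = if (is.null(cfg$filtration)) "" else cfg$filtration)
  geometry <- GeometrySetup(
    sidCm = cfg$sid_cm, sddCm = cfg$sdd_cm,
    objectPlaneOffsetCm = if (is.null(cfg$object_plane_offset_cm)) 0
      else cfg$object_plane_offset_cm,
    beamMode = cfg$beam_mode,
    magnificationAxis = if (is.null(cfg$magnification_axis)) {
      if (cfg$beam_mode == "slot") "none" else "measured_axis"
    } else cfg$magnification_axis)
  list(meta = meta, geometry = geometry,
       pixelPitchMm = as.numeric(cfg$pixel_pitch_mm))
}

#' Magnification from geometry
#'
#' \eqn{m = SID / (SID - offset)} for the measured axis;
#' 1 when the measured axis is the (unmagnified) scan direction
#' (\code{magnificationAxis = "none"}).
#'
#' @param geometry a \linkS4class{GeometrySetup}.
#' @return numeric magnification, >= 1.
#' @export
magnification <- function(geometry) {
  if (geometry@magnificationAxis == "none") return(1)
  geometry@sidCm / (geometry@sidCm - geometry@objectPlaneOffsetCm)
}
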