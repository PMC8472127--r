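#' @import methods
NULL

#' Acquisition metadata for a radiographic exposure
#'
#' Holds the protocol-level acquisition parameters of a single exposure:
#' which system produced it, the examination protocol, tube voltage, tube
#' load, scan speed (slot-scan systems only) and source-to-image distance.
#'
#' @slot systemId character label for the imaging system.
#' @slot protocol examination protocol, one of \code{"chest"}, \code{"knee"}
#'   or \code{""} when not applicable.
#' @slot tubeVoltageKv tube voltage in kV, positive.
#' @slot tubeLoadMas tube load in mAs (\code{NA} for systems driven by scan
#'   speed instead of mAs).
#' @slot scanSpeed integer scan speed for slot-scan systems (\code{NA}
#'   otherwise).
#' @slot sidCm source-to-image distance in cm, positive.
#' @slot filtration free-text additional filtration label (e.g. "0/0.1"
#'   for Al/Cu mm).
#' @exportClass AcquisitionMeta
setClass("AcquisitionMeta",
  representation(
    systemId = "character",
    protocol = "character",
    tubeVoltageKv = "numeric",
    tubeLoadMas = "numeric",
    scanSpeed = "numeric",
    sidCm = "numeric",
    filtration = "character"
  ),
  prototype(
    systemId = "unknown", protocol = "", tubeVoltageKv = 100,
    tubeLoadMas = NA_real_, scanSpeed = NA_real_, sidCm = 100,
    filtration = ""
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@tubeVoltageKv) != 1 ||
        (!is.na(object@tubeVoltageKv) &&
         (!is.finite(object@tubeVoltageKv) || object@tubeVoltageKv <= 0)))
      msg <- c(msg, "tubeVoltageKv must be a positive scalar (or NA if unknown)")
    if (length(object@sidCm) != 1 || !is.finite(object@sidCm) ||
        object@sidCm <= 0)
      msg <- c(msg, "sidCm must be a positive scalar")
    if (!object@protocol %in% c("chest", "knee", ""))
      msg <- c(msg, "protocol must be 'chest', 'knee' or ''")
    if (length(msg)) msg else TRUE
  }
)

#' Construct acquisition metadata
#'
#' @param systemId,protocol,tubeVoltageKv,tubeLoadMas,scanSpeed,sidCm,filtration
#'   see the slots of \linkS4class{AcquisitionMeta}.
#' @return An \linkS4class{AcquisitionMeta} object.
#' @export
AcquisitionMeta <- function(systemId = "unknown", protocol = "",
                            tubeVoltageKv = 100, tubeLoadMas = NA_real_,
                            scanSpeed = NA_real_, sidCm = 100,
                            filtration = "") {
  new("AcquisitionMeta", systemId = as.character(systemId),
      protocol = as.character(protocol),
      tubeVoltageKv = as.numeric(tubeVoltageKv),
      tubeLoadMas = as.numeric(tubeLoadMas),
      scanSpeed = as.numeric(scanSpeed), sidCm = as.numeric(sidCm),
      filtration = as.character(filtration))
}

#' Raw or linearized radiographic image
#'
#' The unit every pipeline stage consumes: a 2D pixel matrix plus the
#' detector pixel pitch and acquisition metadata. Row index increases
#' downward (the vertical / scan direction), column index rightward.
#' Pixel values are either raw detector units (\code{linearized = FALSE})
#' or kerma-proportional units after response inversion.
#'
#' @slot pixels numeric matrix of non-negative, finite pixel values with at
#'   least 2 rows and 2 columns.
#' @slot pixelPitchMm detector pixel pitch in mm, positive.
#' @slot linearized logical flag; \code{TRUE} once the detector response has
#'   been inverted.
#' @slot meta an \linkS4class{AcquisitionMeta}.
#' @exportClass RadiographImage
setClass("RadiographImage",
  representation(
    pixels = "matrix",
    pixelPitchMm = "numeric",
    linearized = "logical",
    meta = "AcquisitionMeta"
  ),
  validity = function(object) {
    msg <- character()
    p <- object@pixels
    if (!is.numeric(p) || nrow(p) < 2 || ncol(p) < 2)
      msg <- c(msg, "pixels must be a numeric matrix with >= 2 rows and columns")
    else if (!all(is.finite(p)))
      msg <- c(msg, "all pixel values must be finite")
    else if (any(p < 0))
      msg <- c(msg, "pixel values must be non-negative")
    if (length(object@pixelPitchMm) != 1 || !is.finite(object@pixelPitchMm) ||
        object@pixelPitchMm <= 0)
      msg <- c(msg, "pixelPitchMm must be a positive scalar")
    if (length(object@linearized) != 1 || is.na(object@linearized))
      msg <- c(msg, "linearized must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a radiographic image
#'
#' @param pixels numeric matrix of pixel values.
#' @param pixelPitchMm pixel pitch in mm.
#' @param linearized whether the pixel values are already kerma-proportional.
#' @param meta an \linkS4class{AcquisitionMeta}.
#' @return A \linkS4class{RadiographImage}.
#' @export
RadiographImage <- function(pixels, pixelPitchMm, linearized = FALSE,
                            meta = AcquisitionMeta()) {
  storage.mode(pixels) <- "double"
  new("RadiographImage", pixels = pixels,
      pixelPitchMm = as.numeric(pixelPitchMm),
      linearized = isTRUE(linearized), meta = meta)
}

#' Measurement geometry of an acquisition
#'
#' Distances are stored in cm (the unit used in protocol configuration
#' files); helpers convert to mm where needed. \code{objectPlaneOffsetCm}
#' is the distance from the detector plane to the object (edge) plane and
#' drives the magnification \eqn{m = SID / (SID - offset)} used to rescale
#' detector-plane frequencies to the object plane.
#'
#' @slot sidCm source-to-image-detector distance, cm.
#' @slot sddCm source-to-dosimeter distance, cm; must not exceed sidCm.
#' @slot objectPlaneOffsetCm detector-to-object-plane distance, cm.
#' @slot beamMode \code{"slot"} (scanning fan beam, linear dose-distance
#'   falloff) or \code{"cone"} (inverse-square falloff).
#' @slot magnificationAxis \code{"measured_axis"} when the measured axis is
#'   magnified by m, \code{"none"} when it has unit magnification (the
#'   scan direction of a slot scanner).
#' @exportClass GeometrySetup
setClass("GeometrySetup",
  representation(
    sidCm = "numeric",
    sddCm = "numeric",
    objectPlaneOffsetCm = "numeric",
    beamMode = "character",
    magnificationAxis = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (!(object@sddCm > 0 && object@sddCm <= object@sidCm))
      msg <- c(msg, "require 0 < sddCm <= sidCm")
    if (!(object@objectPlaneOffsetCm >= 0 &&
          object@objectPlaneOffsetCm < object@sidCm))
      msg <- c(msg, "require 0 <= objectPlaneOffsetCm < sidCm")
    if (!object@beamMode %in% c("slot", "cone"))
      msg <- c(msg, "beamMode must be 'slot' or 'cone'")
    if (!object@magnificationAxis %in% c("measured_axis", "none"))
      msg <- c(msg, "magnificationAxis must be 'measured_axis' or 'none'")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a measurement geometry
#'
#' @param sidCm,sddCm,objectPlaneOffsetCm,beamMode,magnificationAxis see the
#'   slots of \linkS4class{GeometrySetup}.
#' @return A \linkS4class{GeometrySetup}.
#' @export
GeometrySetup <- function(sidCm, sddCm = sidCm, objectPlaneOffsetCm = 0,
                          beamMode = c("cone", "slot"),
                          magnificationAxis = c("measured_axis", "none")) {
  new("GeometrySetup", sidCm = as.numeric(sidCm), sddCm = as.numeric(sddCm),
      objectPlaneOffsetCm = as.numeric(objectPlaneOffsetCm),
      beamMode = match.arg(beamMode),
      magnificationAxis = match.arg(magnificationAxis))
}

#' Uniformly sampled frequency-domain curve
#'
#' Carrier for eMTF, eNNPS, eNEQ and eDQE curves: a uniform ascending
#' frequency grid starting at 0 (mm^-1), the curve values, the reference
#' plane the frequencies refer to, and a quantity tag.
#'
#' @slot frequencies ascending uniform grid in mm^-1, starting at 0.
#' @slot values numeric curve values, same length as frequencies.
#' @slot plane \code{"detector"} or \code{"object"}.
#' @slot quantity one of \code{"eMTF"}, \code{"eNNPS"}, \code{"eDQE"},
#'   \code{"eNEQ"}.
#' @exportClass FrequencySeries
setClass("FrequencySeries",
  representation(
    frequencies = "numeric",
    values = "numeric",
    plane = "character",
    quantity = "character"
  ),
  validity = function(object) {
    msg <- character()
    f <- object@frequencies
    if (length(f) < 2)
      msg <- c(msg, "need at least 2 frequency samples")
    else {
      if (abs(f[1]) > 1e-9) msg <- c(msg, "frequencies must start at 0")
      d <- diff(f)
      if (any(d <= 0)) msg <- c(msg, "frequencies must be strictly ascending")
      if (max(d) - min(d) > 1e-9)
        msg <- c(msg, "frequency spacing must be uniform within 1e-9")
    }
    if (length(object@values) != length(f))
      msg <- c(msg, "values must have the same length as frequencies")
    if (!object@plane %in% c("detector", "object"))
      msg <- c(msg, "plane must be 'detector' or 'object'")
    if (!object@quantity %in% c("eMTF", "eNNPS", "eDQE", "eNEQ"))
      msg <- c(msg, "quantity must be one of eMTF, eNNPS, eDQE, eNEQ")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a frequency series
#'
#' @param frequencies ascending uniform grid in mm^-1 starting at 0.
#' @param values curve values.
#' @param plane reference plane, \code{"detector"} or \code{"object"}.
#' @param quantity curve tag: \code{"eMTF"}, \code{"eNNPS"}, \code{"eDQE"}
#'   or \code{"eNEQ"}.
#' @return A \linkS4class{FrequencySeries}.
#' @export
FrequencySeries <- function(frequencies, values, plane = "detector",
                            quantity = "eMTF") {
  new("FrequencySeries", frequencies = as.numeric(frequencies),
      values = as.numeric(values), plane = plane, quantity = quantity)
}

#' Fitted detector response model
#'
#' Least-squares fit of mean pixel value against detector air kerma, either
#' linear or fifth-order polynomial, constrained to be strictly monotone
#' increasing over its fitted kerma range so that it can be inverted to
#' linearize images.
#'
#' @slot kind \code{"linear"} or \code{"polynomial5"}.
#' @slot coefficients polynomial coefficients, intercept first.
#' @slot validRangeUGy fitted kerma range (min, max) in uGy.
#' @slot rSquared coefficient of determination of the fit.
#' @exportClass ResponseModel
setClass("ResponseModel",
  representation(
    kind = "character",
    coefficients = "numeric",
    validRangeUGy = "numeric",
    rSquared = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("linear", "polynomial5"))
      msg <- c(msg, "kind must be 'linear' or 'polynomial5'")
    if (length(object@validRangeUGy) != 2 ||
        object@validRangeUGy[1] >= object@validRangeUGy[2])
      msg <- c(msg, "validRangeUGy must be an increasing (min, max) pair")
    if (!is.finite(object@rSquared))
      msg <- c(msg, "rSquared must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Ground truth record of a synthetic image
#'
#' Every synthetic generator returns, next to the image, the exact
#' parameters a downstream estimator should recover: the Gaussian PSF width
#' behind an edge image, the flat NNPS level behind a flat field, the
#' scatter fraction behind a beam-stop image, or the detector response
#' coefficients behind an exposure series. Fields not produced by the
#' generating call are \code{NA} / empty.
#'
#' @slot trueMtfSigmaMm Gaussian PSF sigma in mm (edge images).
#' @slot trueEdgeAngleDeg nominal edge tilt in degrees (edge images).
#' @slot trueNnpsLevelMm2 flat NNPS level sigma^2 pitch^2 / mean^2 in mm^2
#'   (flat fields).
#' @slot trueSf scatter fraction in [0, 1) (beam-stop images).
#' @slot responseCoeffs response polynomial coefficients, intercept first
#'   (exposure series).
#' @slot seed integer seed the generator was called with.
#' @exportClass SyntheticGroundTruth
setClass("SyntheticGroundTruth",
  representation(
    trueMtfSigmaMm = "numeric",
    trueEdgeAngleDeg = "numeric",
    trueNnpsLevelMm2 = "numeric",
    trueSf = "numeric",
    responseCoeffs = "numeric",
    seed = "numeric"
  ),
  prototype(
    trueMtfSigmaMm = NA_real_, trueEdgeAngleDeg = NA_real_,
    trueNnpsLevelMm2 = NA_real_, trueSf = NA_real_,
    responseCoeffs = numeric(0), seed = NA_real_
  ),
  validity = function(object) {
    if (!is.na(object@trueSf) &&
        (object@trueSf < 0 || object@trueSf >= 1))
      "trueSf must lie in [0, 1)" else TRUE
  }
)

#' Beam-stop grid specification
#'
#' Geometry of the beam-stop device: a rectangular array of lead cylinders
#' embedded in PMMA, rendered as hard opaque disks by the synthetic
#' generator and used as the sampling template by the scatter-fraction
#' analyzer.
#'
#' @slot nRows,nCols number of cylinders per direction (>= 5 so a central
#'   5x5 block exists); the physical device is an 11 x 11 array.
#' @slot pitchMm center-to-center spacing in mm; must exceed the diameter.
#' @slot cylinderDiameterMm cylinder (shadow) diameter in mm.
#' @slot centerOffsetMm length-2 (row, col) offset of the grid center from
#'   the image center, mm.
#' @exportClass BeamStopGridSpec
setClass("BeamStopGridSpec",
  representation(
    nRows = "numeric",
    nCols = "numeric",
    pitchMm = "numeric",
    cylinderDiameterMm = "numeric",
    centerOffsetMm = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@nRows < 5 || object@nCols < 5)
      msg <- c(msg, "nRows and nCols must be >= 5 (central 5x5 block needed)")
    if (object@pitchMm <= object@cylinderDiameterMm)
      msg <- c(msg, "pitchMm must exceed cylinderDiameterMm")
    if (length(object@centerOffsetMm) != 2)
      msg <- c(msg, "centerOffsetMm must have length 2 (row, col)")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a beam-stop grid specification
#'
#' @param nRows,nCols,pitchMm,cylinderDiameterMm,centerOffsetMm see the
#'   slots of \linkS4class{BeamStopGridSpec}.
#' @return A \linkS4class{BeamStopGridSpec}.
#' @export
BeamStopGridSpec <- function(nRows = 11, nCols = 11, pitchMm = 15,
                             cylinderDiameterMm = 3,
                             centerOffsetMm = c(0, 0)) {
  new("BeamStopGridSpec", nRows = as.numeric(nRows), nCols = as.numeric(nCols),
      pitchMm = as.numeric(pitchMm),
      cylinderDiameterMm = as.numeric(cylinderDiameterMm),
      centerOffsetMm = as.numeric(centerOffsetMm))
}

#' Tabulated X-ray spectrum
#'
#' Photon fluence per unit area against energy on a uniform energy grid.
#' The absolute fluence scale may be relative: the q-value is invariant to
#' it.
#'
#' @slot energiesKev ascending, uniform energy bin centers in keV.
#' @slot fluencePerMm2 non-negative fluence per mm^2 (per mAs, relative
#'   scale allowed).
#' @slot binWidthKev energy bin width in keV.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    energiesKev = "numeric",
    fluencePerMm2 = "numeric",
    binWidthKev = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    e <- object@energiesKev
    if (length(e) < 1 || any(diff(e) <= 0))
      msg <- c(msg, "energies must be ascending")
    if (length(e) > 1 && diff(range(diff(e))) > 1e-9)
      msg <- c(msg, "energy grid must be uniform")
    if (length(object@fluencePerMm2) != length(e))
      msg <- c(msg, "fluence must match energy grid length")
    else if (any(object@fluencePerMm2 < 0))
      msg <- c(msg, "fluence must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a spectrum
#'
#' @param energiesKev,fluencePerMm2,binWidthKev see the slots of
#'   \linkS4class{Spectrum}.
#' @return A \linkS4class{Spectrum}.
#' @export
Spectrum <- function(energiesKev, fluencePerMm2,
                     binWidthKev = if (length(energiesKev) > 1)
                       diff(energiesKev[1:2]) else 1) {
  new("Spectrum", energiesKev = as.numeric(energiesKev),
      fluencePerMm2 = as.numeric(fluencePerMm2),
      binWidthKev = as.numeric(binWidthKev))
}

#' Two-dimensional noise power spectrum
#'
#' The 2D effective normalised noise power spectrum (eNNPS) of a set of
#' linearized flat-field images, on symmetric detector-plane frequency
#' axes, in mm^2.
#'
#' @slot u horizontal frequency axis, mm^-1, symmetric about 0.
#' @slot v vertical frequency axis, mm^-1 (rows of the matrix).
#' @slot nnps matrix of NNPS values (rows index v, columns u), mm^2.
#' @slot nSubrois number of sub-ROIs averaged.
#' @slot meanSignal mean linearized signal over the analysis ROI.
#' @slot pixelPitchMm detector pixel pitch, mm.
#' @exportClass Nnps2D
setClass("Nnps2D",
  representation(
    u = "numeric",
    v = "numeric",
    nnps = "matrix",
    nSubrois = "numeric",
    meanSignal = "numeric",
    pixelPitchMm = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (any(object@nnps < 0))
      msg <- c(msg, "NNPS values must be non-negative")
    if (nrow(object@nnps) != length(object@v) ||
        ncol(object@nnps) != length(object@u))
      msg <- c(msg, "nnps dimensions must match the u/v axes")
    if (length(msg)) msg else TRUE
  }
)

#' Dosimeter readings with and without the phantom
#'
#' @slot akWithPhantomUGy air kerma measured with the phantom in the beam
#'   (narrow-beam geometry), uGy.
#' @slot akWithoutPhantomUGy phantom-free air kerma, uGy; at least
#'   \code{akWithPhantomUGy}.
#' @slot sddCm source-to-dosimeter distance, cm.
#' @slot sidCm source-to-image-detector distance, cm.
#' @slot beamMode \code{"slot"} or \code{"cone"}.
#' @exportClass DoseReadings
setClass("DoseReadings",
  representation(
    akWithPhantomUGy = "numeric",
    akWithoutPhantomUGy = "numeric",
    sddCm = "numeric",
    sidCm = "numeric",
    beamMode = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (!(object@akWithPhantomUGy > 0) || !(object@akWithoutPhantomUGy > 0))
      msg <- c(msg, "air-kerma readings must be positive")
    if (object@akWithPhantomUGy > object@akWithoutPhantomUGy)
      msg <- c(msg, "akWithPhantomUGy must not exceed akWithoutPhantomUGy")
    if (!object@beamMode %in% c("slot", "cone"))
      msg <- c(msg, "beamMode must be 'slot' or 'cone'")
    if (length(msg)) msg else TRUE
  }
)

#' Construct dosimeter readings
#'
#' @param akWithPhantomUGy,akWithoutPhantomUGy,sddCm,sidCm,beamMode see the
#'   slots of \linkS4class{DoseReadings}.
#' @return A \linkS4class{DoseReadings}.
#' @export
DoseReadings <- function(akWithPhantomUGy, akWithoutPhantomUGy, sddCm, sidCm,
                         beamMode = c("cone", "slot")) {
  new("DoseReadings", akWithPhantomUGy = as.numeric(akWithPhantomUGy),
      akWithoutPhantomUGy = as.numeric(akWithoutPhantomUGy),
      sddCm = as.numeric(sddCm), sidCm = as.numeric(sidCm),
      beamMode = match.arg(beamMode))
}

#' Beam-stop scatter-fraction measurement result
#'
#' @slot sf scatter fraction, the ratio of the mean attenuated signal
#'   behind the central lead cylinders to the mean background signal.
#' @slot mpvLead mean linearized pixel value behind the sampled cylinders.
#' @slot mpvBackground mean linearized pixel value between them.
#' @slot nCylindersUsed number of cylinders sampled (25: the central 5x5).
#' @exportClass ScatterResult
setClass("ScatterResult",
  representation(
    sf = "numeric",
    mpvLead = "numeric",
    mpvBackground = "numeric",
    nCylindersUsed = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (!(object@sf >= 0 && object@sf < 1))
      msg <- c(msg, "sf must lie in [0, 1)")
    if (abs(object@sf - object@mpvLead / object@mpvBackground) >
        1e-9 * max(1, abs(object@sf)))
      msg <- c(msg, "sf must equal mpvLead / mpvBackground")
    if (length(msg)) msg else TRUE
  }
)

#' Per-system measurement bundle for metric composition
#'
#' Everything the eDQE composition needs for one system/protocol: the
#' object-plane eMTF and eNNPS on a common frequency grid, the scatter
#' fraction SF, transmission factor TF, the phantom-free air kerma
#' corrected to the detector plane (uGy), and the photon fluence per air
#' kerma q (mm^-2 uGy^-1).
#'
#' @slot emtf object-plane eMTF \linkS4class{FrequencySeries}.
#' @slot ennps object-plane eNNPS \linkS4class{FrequencySeries} (mm^2).
#' @slot sf scatter fraction in [0, 1).
#' @slot tf transmission factor in (0, 1].
#' @slot akUGy phantom-free air kerma corrected to the detector plane, uGy.
#' @slot qPerUGyMm2 photon fluence per air kerma, mm^-2 uGy^-1.
#' @slot meta an \linkS4class{AcquisitionMeta}.
#' @exportClass SystemMeasurement
setClass("SystemMeasurement",
  representation(
    emtf = "FrequencySeries",
    ennps = "FrequencySeries",
    sf = "numeric",
    tf = "numeric",
    akUGy = "numeric",
    qPerUGyMm2 = "numeric",
    meta = "AcquisitionMeta"
  ),
  validity = function(object) {
    msg <- character()
    fe <- object@emtf@frequencies
    fn <- object@ennps@frequencies
    if (length(fe) != length(fn) || max(abs(fe - fn)) > 1e-9)
      msg <- c(msg, "eMTF and eNNPS must share an identical frequency grid")
    if (!(object@sf >= 0 && object@sf < 1))
      msg <- c(msg, "sf must lie in [0, 1)")
    if (!(object@tf > 0 && object@tf <= 1))
      msg <- c(msg, "tf must lie in (0, 1]")
    if (!(object@akUGy > 0)) msg <- c(msg, "akUGy must be positive")
    if (!(object@qPerUGyMm2 > 0)) msg <- c(msg, "qPerUGyMm2 must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a per-system measurement bundle
#'
#' @param emtf,ennps,sf,tf,akUGy,qPerUGyMm2,meta see the slots of
#'   \linkS4class{SystemMeasurement}.
#' @return A \linkS4class{SystemMeasurement}.
#' @export
SystemMeasurement <- function(emtf, ennps, sf, tf, akUGy, qPerUGyMm2,
                              meta = AcquisitionMeta()) {
  new("SystemMeasurement", emtf = emtf, ennps = ennps, sf = as.numeric(sf),
      tf = as.numeric(tf), akUGy = as.numeric(akUGy),
      qPerUGyMm2 = as.numeric(qPerUGyMm2), meta = meta)
}

#' Rank-based inter-system comparison report
#'
#' Structured result of the stratified nonparametric comparison of metric
#' curves across systems: one Kruskal-Wallis row per frequency bin, and
#' (when the global test is significant at the chosen level) pairwise
#' Mann-Whitney rows for every system pair in that bin. No multiplicity
#' adjustment is applied; adjacent frequency samples are statistically
#' dependent, so the tests are exploratory/anti-conservative.
#'
#' @slot metric \code{"eDQE"} or \code{"eNEQ"}.
#' @slot kruskal data.frame with columns bin, lo, hi, n, H, df, p.
#' @slot pairwise data.frame with columns bin, pair, U, Z, p (empty when
#'   the global test was not significant in any bin).
#' @slot alpha significance level of the hierarchical gate.
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  representation(
    metric = "character",
    kruskal = "data.frame",
    pairwise = "data.frame",
    alpha = "numeric"
  )
)

#' Edge-analysis configuration
#'
#' Tuning parameters of the slanted-edge eMTF estimator.
#'
#' @slot roiSizeMm analysis ROI side length, mm (80 mm default).
#' @slot esfBinFraction super-sampling bin width as a fraction of the pixel
#'   pitch (0.1 default).
#' @slot nImages number of edge images averaged (5 default).
#' @slot window \code{"hann"} (on the LSF, centered on its peak) or
#'   \code{"none"}.
#' @slot derivative ESF differentiation scheme; \code{"central_difference"}.
#' @slot compensate logical; divide the MTF by the known transfer of the
#'   super-sampling bin box and the central-difference kernel.
#' @exportClass EdgeAnalysisConfig
setClass("EdgeAnalysisConfig",
  representation(
    roiSizeMm = "numeric",
    esfBinFraction = "numeric",
    nImages = "numeric",
    window = "character",
    derivative = "character",
    compensate = "logical"
  ),
  validity = function(object) {
    msg <- character()
    if (!(object@esfBinFraction > 0 && object@esfBinFraction <= 0.5))
      msg <- c(msg, "esfBinFraction must lie in (0, 0.5]")
    if (!object@window %in% c("hann", "none"))
      msg <- c(msg, "window must be 'hann' or 'none'")
    if (!identical(object@derivative, "central_difference"))
      msg <- c(msg, "derivative must be 'central_difference'")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an edge-analysis configuration
#'
#' @param roiSizeMm,esfBinFraction,nImages,window,derivative,compensate see
#'   the slots of \linkS4class{EdgeAnalysisConfig}.
#' @return An \linkS4class{EdgeAnalysisConfig}.
#' @export
EdgeAnalysisConfig <- function(roiSizeMm = 80, esfBinFraction = 0.1,
                               nImages = 5, window = c("hann", "none"),
                               derivative = "central_difference",
                               compensate = TRUE) {
  new("EdgeAnalysisConfig", roiSizeMm = as.numeric(roiSizeMm),
      esfBinFraction = as.numeric(esfBinFraction), nImages = as.numeric(nImages),
      window = match.arg(window), derivative = derivative,
      compensate = isTRUE(compensate))
}

#' Super-sampled edge spread function
#'
#' @slot positionsMm uniform super-sampled signed distances to the fitted
#'   edge line, mm.
#' @slot values mean linearized pixel value per bin.
#' @slot binCounts number of contributing pixels per bin (0 marks bins
#'   filled by interpolation).
#' @slot binWidthMm super-sampling bin width, mm.
#' @exportClass EsfProfile
setClass("EsfProfile",
  representation(
    positionsMm = "numeric",
    values = "numeric",
    binCounts = "numeric",
    binWidthMm = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    n <- length(object@positionsMm)
    if (length(object@values) != n || length(object@binCounts) != n)
      msg <- c(msg, "positions, values and binCounts must share a length")
    if (n > 1) {
      d <- diff(object@positionsMm)
      if (any(d <= 0) || max(abs(d - object@binWidthMm)) > 1e-9)
        msg <- c(msg, "positions must ascend uniformly at binWidthMm")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Noise-power-spectrum analysis configuration
#'
#' @slot roiPx side of the central analysis ROI in pixels (1024 default).
#' @slot subPx side of the square sub-ROIs (256 default).
#' @slot overlapPx overlap of adjacent sub-ROIs in both directions (128
#'   default).
#' @slot nImages number of flat-field images expected (4 default).
#' @slot detrend \code{"poly2d"} (subtract a per-sub-ROI 2D quadratic
#'   surface) or \code{"mean"}.
#' @slot bandLines half-width, in frequency columns, of the band flanking
#'   the vertical frequency axis that is averaged into the 1D curve.
#' @slot excludeAxis logical; drop the on-axis (u = 0) column from the 1D
#'   average.
#' @exportClass NnpsConfig
setClass("NnpsConfig",
  representation(
    roiPx = "numeric",
    subPx = "numeric",
    overlapPx = "numeric",
    nImages = "numeric",
    detrend = "character",
    bandLines = "numeric",
    excludeAxis = "logical"
  ),
  validity = function(object) {
    msg <- character()
    step <- object@subPx - object@overlapPx
    if (step <= 0)
      msg <- c(msg, "overlapPx must be smaller than subPx")
    else if ((object@roiPx - object@subPx) %% step != 0)
      msg <- c(msg, "(roiPx - subPx) must be divisible by (subPx - overlapPx)")
    if (!object@detrend %in% c("poly2d", "mean"))
      msg <- c(msg, "detrend must be 'poly2d' or 'mean'")
    if (object@bandLines < 1)
      msg <- c(msg, "bandLines must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an NNPS analysis configuration
#'
#' @param roiPx,subPx,overlapPx,nImages,detrend,bandLines,excludeAxis see
#'   the slots of \linkS4class{NnpsConfig}.
#' @return An \linkS4class{NnpsConfig}.
#' @export
NnpsConfig <- function(roiPx = 1024, subPx = 256, overlapPx = 128,
                       nImages = 4, detrend = c("poly2d", "mean"),
                       bandLines = 7, excludeAxis = TRUE) {
  if (subPx > 1 && bitwAnd(as.integer(subPx), as.integer(subPx) - 1L) != 0L)
    warning("subPx is not a power of two; FFTs will be slower")
  new("NnpsConfig", roiPx = as.numeric(roiPx), subPx = as.numeric(subPx),
      overlapPx = as.numeric(overlapPx), nImages = as.numeric(nImages),
      detrend = match.arg(detrend), bandLines = as.numeric(bandLines),
      excludeAxis = isTRUE(excludeAxis))
}

#' Frequency-bin specification for the stratified comparison
#'
#' Low/high frequency ranges used to stratify metric curves before the
#' rank-based tests. Defaults: eDQE 0.00-1.00 and 1.15-2.15 mm^-1; eNEQ
#' 0.00-1.25 and 1.35-2.55 mm^-1.
#'
#' @slot metric \code{"eDQE"} or \code{"eNEQ"}.
#' @slot lowRange length-2 ascending range, mm^-1.
#' @slot highRange length-2 ascending range, disjoint from and above
#'   lowRange.
#' @exportClass FreqBinSpec
setClass("FreqBinSpec",
  representation(
    metric = "character",
    lowRange = "numeric",
    highRange = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (!object@metric %in% c("eDQE", "eNEQ"))
      msg <- c(msg, "metric must be 'eDQE' or 'eNEQ'")
    if (diff(object@lowRange) <= 0 || diff(object@highRange) <= 0)
      msg <- c(msg, "ranges must be ascending")
    if (object@lowRange[2] >= object@highRange[1])
      msg <- c(msg, "ranges must be disjoint and ascending")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a frequency-bin specification
#'
#' @param metric \code{"eDQE"} or \code{"eNEQ"}; selects the default bins.
#' @param lowRange,highRange optional explicit ranges, mm^-1.
#' @return A \linkS4class{FreqBinSpec}.
#' @export
FreqBinSpec <- function(metric = c("eDQE", "eNEQ"), lowRange = NULL,
                        highRange = NULL) {
  metric <- match.arg(metric)
  if (is.null(lowRange))
    lowRange <- if (metric == "eDQE") c(0, 1) else c(0, 1.25)
  if (is.null(highRange))
    highRange <- if (metric == "eDQE") c(1.15, 2.15) else c(1.35, 2.55)
  new("FreqBinSpec", metric = metric, lowRange = as.numeric(lowRange),
      highRange = as.numeric(highRange))
}
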