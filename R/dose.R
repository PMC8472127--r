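#' Transmission factor through the phantom
#'
#' \eqn{TF = AK_+ / AK_-}: the ratio of the narrow-beam air kerma measured
#' with the phantom in the beam to the phantom-free reading.
#'
#' @param readings a \linkS4class{DoseReadings}.
#' @return TF in (0, 1].
#' @examples
#' transmissionFactor(DoseReadings(1.2, 10, 250, 300))  # 0.12
#' @export
transmissionFactor <- function(readings) {
  validObject(readings)
  readings@akWithPhantomUGy / readings@akWithoutPhantomUGy
}

#' Incident air kerma at the detector plane distance
#'
#' Corrects a dosimeter reading from the source-to-dosimeter distance
#' (SDD) to the source-to-image distance (SID). A slot-scanned fan beam
#' diverges in one direction only, so its dose falls off linearly with
#' distance (\eqn{IAK = AK \cdot SDD/SID}); a cone beam follows the
#' inverse square law (\eqn{IAK = AK \cdot (SDD/SID)^2}).
#'
#' @param akMeasuredUGy dosimeter reading, uGy.
#' @param readings a \linkS4class{DoseReadings} supplying SDD, SID and the
#'   beam mode.
#' @return IAK, uGy.
#' @examples
#' rd <- DoseReadings(5, 10, sddCm = 65, sidCm = 130, beamMode = "slot")
#' incidentAirKerma(10, rd)  # 5
#' @export
incidentAirKerma <- function(akMeasuredUGy, readings) {
  if (readings@sddCm > readings@sidCm)
    stopf("validation error: SDD (%g cm) exceeds SID (%g cm)",
          readings@sddCm, readings@sidCm)
  ratio <- readings@sddCm / readings@sidCm
  if (readings@beamMode == "slot") akMeasuredUGy * ratio
  else akMeasuredUGy * ratio^2
}

#' Air kerma at the detector plane
#'
#' \eqn{DAK = IAK \cdot TF}.
#'
#' @param iakUGy incident air kerma, uGy.
#' @param tf transmission factor in (0, 1].
#' @return DAK, uGy.
#' @examples
#' detectorAirKerma(16.40, 0.12)  # 1.968 -> prints as 1.97
#' @export
detectorAirKerma <- function(iakUGy, tf) {
  if (!(tf > 0 && tf <= 1))
    stopf("validation error: TF must lie in (0, 1], got %g", tf)
  iakUGy * tf
}
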