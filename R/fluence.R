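# Photon fluence per air kerma. Air kerma from a fluence spectrum:
# K = sum_E Phi(E) E (mu_en/rho)_air(E) u, with u the single unit
# conversion constant keV cm^2 g^-1 mm^-2 -> uGy:
# 1 keV = 1.602176634e-16 J, cm^2 = 100 mm^2, J/g = 1e3 Gy = 1e9 uGy
# => u = 1.602176634e-16 * 100 * 1e9 uGy = 1.602176634e-5 uGy.
.KEV_CM2_PER_G_MM2_TO_UGY <- 1.602176634e-5

#' Air mass energy-absorption coefficient table
#'
#' The shipped NIST-derived \eqn{(\mu_{en}/\rho)_{air}} tabulation over
#' 10-200 keV, interpolated log-log between grid points.
#'
#' @return data.frame with columns \code{energy_keV} and
#'   \code{muen_over_rho_cm2_per_g}.
#' @export
muEnAirTable <- function() {
  utils::read.csv(system.file("extdata", "muen_air.csv", package = "effiq"),
                  comment.char = "#")
}

#' Air kerma delivered by a fluence spectrum
#'
#' \eqn{K = \sum_E \Phi(E)\,E\,(\mu_{en}/\rho)_{air}(E)\,u} over the
#' spectrum bins, on the spectrum's own fluence scale (per mAs when the
#' fluence is per mAs).
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param table air coefficient table as from \code{\link{muEnAirTable}}.
#' @return air kerma in uGy (per the spectrum's fluence scale).
#' @export
airKermaFromSpectrum <- function(spectrum, table = muEnAirTable()) {
  e <- spectrum@energiesKev
  fl <- spectrum@fluencePerMm2
  if (!length(e) || all(fl == 0)) return(0)
  muen <- interpLogLog(table$energy_keV, table$muen_over_rho_cm2_per_g, e)
  sum(fl * e * muen) * .KEV_CM2_PER_G_MM2_TO_UGY
}

#' Photon fluence per air kerma (q-value)
#'
#' \eqn{q = \Phi_{tot} / K}: the total photon fluence of the spectrum
#' divided by the air kerma it delivers. Scale-invariant in the fluence,
#' so relative spectra are fine. For a monoenergetic beam this reduces to
#' \eqn{1 / (E \, (\mu_{en}/\rho)_{air}(E) \, u)}.
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param table air coefficient table as from \code{\link{muEnAirTable}}.
#' @return list with \code{q} (mm^-2 uGy^-1), \code{phiTot} and
#'   \code{akUGy} (both on the spectrum's fluence scale).
#' @examples
#' s <- Spectrum(60, 1)             # monoenergetic 60 keV
#' qValue(s)$q                      # ~3.4e4 mm^-2 uGy^-1
#' @export
qValue <- function(spectrum, table = muEnAirTable()) {
  phiTot <- sum(spectrum@fluencePerMm2)
  ak <- airKermaFromSpectrum(spectrum, table)
  if (ak <= 0) stopf("division error: spectrum delivers zero air kerma")
  list(q = phiTot / ak, phiTot = phiTot, akUGy = ak)
}
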