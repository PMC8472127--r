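# End-to-end protocol runs. In synthetic mode every input image class is
# generated with known ground truth (exposure series, slanted edges, flat
# fields, beam-stop grid, spectrum), then measured by exactly the same
# estimators a measured-mode run would use: detector response -> eMTF ->
# eNNPS -> scatter/dose -> q -> eNEQ/eDQE -> rank-based comparison.

.runStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
}

# Map a kerma-domain synthetic image through the forward response into
# raw detector units (plus raw-domain noise), undoing the generator's
# linearized flag so the pipeline has to invert the response itself.
.toRawImage <- function(image, coeffs, noiseSd = 0, seed = 1) {
  px <- .polyEval(coeffs, pixels(image))
  if (noiseSd > 0)
    px <- px + withSeed(seed, matrix(stats::rnorm(length(px), sd = noiseSd),
                                     nrow(px), ncol(px)))
  RadiographImage(pmax(px, 0), pixelPitch(image), linearized = FALSE,
                  meta = acquisitionMeta(image))
}

#' Default synthetic system parameters
#'
#' Study-condition parameter sets for three simulated systems (a slot
#' scanner and two flat-panel DR systems) under a chest-like or knee-like
#' protocol: tube voltage/filtration per the exposure settings, scatter
#' fraction, transmission factor and phantom-free air kerma of the
#' magnitudes reported for such systems, a linear detector response, and
#' noise levels that place the flat-field eNNPS at the plateau implied by
#' the target noise-equivalent quanta. The slot system's pixel pitch is a
#' package choice (0.18 mm) so that the comparison band is sampled on all
#' systems.
#'
#' @param systemId \code{"ldss"}, \code{"dr1"} or \code{"dr2"}.
#' @param protocol \code{"chest"} or \code{"knee"}.
#' @return named list of generator and measurement parameters, suitable
#'   for \code{\link{runProtocol}}.
#' @export
syntheticSystemDefaults <- function(systemId = c("ldss", "dr1", "dr2"),
                                    protocol = c("chest", "knee")) {
  systemId <- match.arg(systemId)
  protocol <- match.arg(protocol)
  base <- list(
    systemId = systemId, protocol = protocol,
    edgeAngleDeg = 3, responseCoeffs = c(50, 280),
    dakLevels = seq(0.02, 15, length.out = 10),
    seriesNoiseSd = 8, edgeContrastUGy = c(1, 12),
    flatKermaUGy = 2.5,
    grid = BeamStopGridSpec(11, 11, pitchMm = 8, cylinderDiameterMm = 2.4),
    beamstopNoiseSd = 8, qOverride = NULL
  )
  tab <- list(
    chest = list(
      ldss = list(pixelPitchMm = 0.18, sigmaMm = 0.15, sf = 0.05, tf = 0.10,
                  akWithoutUGy = 13.96, kvp = 90, filtrAl = 0, filtrCu = 0.1,
                  sidCm = 130, beamMode = "slot", flatNoiseSdUGy = 0.191),
      dr1 = list(pixelPitchMm = 0.143, sigmaMm = 0.08, sf = 0.19, tf = 0.12,
                 akWithoutUGy = 16.40, kvp = 133, filtrAl = 1, filtrCu = 0.2,
                 sidCm = 250, beamMode = "cone", flatNoiseSdUGy = 0.247),
      dr2 = list(pixelPitchMm = 0.139, sigmaMm = 0.085, sf = 0.18, tf = 0.11,
                 akWithoutUGy = 15.68, kvp = 145, filtrAl = 0, filtrCu = 0.2,
                 sidCm = 300, beamMode = "cone", flatNoiseSdUGy = 0.253)
    ),
    knee = list(
      ldss = list(pixelPitchMm = 0.18, sigmaMm = 0.15, sf = 0.03, tf = 0.14,
                  akWithoutUGy = 15.72, kvp = 68, filtrAl = 0, filtrCu = 0,
                  sidCm = 130, beamMode = "slot", flatNoiseSdUGy = 0.127),
      dr1 = list(pixelPitchMm = 0.143, sigmaMm = 0.08, sf = 0.28, tf = 0.15,
                 akWithoutUGy = 18.40, kvp = 57, filtrAl = 0, filtrCu = 0,
                 sidCm = 115, beamMode = "cone", flatNoiseSdUGy = 0.176),
      dr2 = list(pixelPitchMm = 0.139, sigmaMm = 0.085, sf = 0.26, tf = 0.16,
                 akWithoutUGy = 17.90, kvp = 63, filtrAl = 0, filtrCu = 0,
                 sidCm = 110, beamMode = "cone", flatNoiseSdUGy = 0.181)
    )
  )
  sys <- tab[[protocol]][[systemId]]
  out <- c(base, sys)
  out$sddCm <- out$sidCm          # dosimeter at the detector plane
  out$objectPlaneOffsetCm <- 0
  out$magnificationAxis <- if (sys$beamMode == "slot") "none"
                           else "measured_axis"
  # raw-domain flat noise matching the target kerma-domain sd
  out$flatNoiseSdRaw <- out$flatNoiseSdUGy * out$responseCoeffs[2]
  out$edgeNoiseSdRaw <- 0.005 * out$responseCoeffs[2] *
    diff(out$edgeContrastUGy)
  out
}

#' Simulate and measure one synthetic system
#'
#' Generates the four synthetic image classes for one parameter set,
#' pushes them through the measurement chain (response fit and
#' linearization, slanted-edge eMTF, flat-field eNNPS, beam-stop scatter
#' fraction, dose geometry, spectrum q) and composes the result into a
#' \linkS4class{SystemMeasurement} plus eNEQ/eDQE curves.
#'
#' @param params parameter list as from
#'   \code{\link{syntheticSystemDefaults}}.
#' @param seed integer seed for every stochastic generator in this
#'   system's run.
#' @param edgeConfig an \linkS4class{EdgeAnalysisConfig}.
#' @param nnpsConfig an \linkS4class{NnpsConfig}.
#' @param gridStep reporting grid step, mm^-1.
#' @param fmax highest reported frequency, mm^-1 (defaults to the largest
#'   step multiple both curves support).
#' @return list with \code{measurement}, \code{edqe}, \code{eneq},
#'   \code{response}, \code{scatter}, \code{summary} (the per-system
#'   numeric log: TF, q, SF, AK, DAK, max eNEQ, max eDQE) and
#'   \code{truth}.
#' @export
measureSyntheticSystem <- function(params, seed = 1,
                                   edgeConfig = EdgeAnalysisConfig(roiSizeMm = 50),
                                   nnpsConfig = NnpsConfig(roiPx = 512),
                                   gridStep = 0.1, fmax = NULL) {
  p <- params
  meta <- AcquisitionMeta(systemId = p$systemId, protocol = p$protocol,
                          tubeVoltageKv = if (is.null(p$kvp)) NA_real_
                                          else p$kvp,
                          sidCm = p$sidCm)
  geometry <- GeometrySetup(sidCm = p$sidCm, sddCm = p$sddCm,
                            objectPlaneOffsetCm = p$objectPlaneOffsetCm,
                            beamMode = p$beamMode,
                            magnificationAxis = p$magnificationAxis)
  pitch <- p$pixelPitchMm

  # -- detector response ----------------------------------------------
  model <- .runStage("detector_response", {
    ser <- makeExposureSeries("linear", p$responseCoeffs, p$dakLevels,
                              pitchMm = pitch, shape = c(64, 64),
                              noiseSd = p$seriesNoiseSd, seed = seed + 11,
                              meta = meta)
    fitResponseFromImages(ser$images, ser$dakUGy, "linear")
  })

  # -- slanted-edge eMTF ----------------------------------------------
  emtfCurve <- .runStage("emtf", {
    roiPxN <- ceiling(edgeConfig@roiSizeMm / pitch) + 8
    edges <- lapply(seq_len(edgeConfig@nImages), function(i) {
      shift <- (i - (edgeConfig@nImages + 1) / 2) * 0.35  # mm between exposures
      ke <- makeEdgeImage(p$edgeAngleDeg, p$sigmaMm, pitch,
                          shape = c(roiPxN, roiPxN),
                          contrast = p$edgeContrastUGy, noiseSd = 0,
                          seed = seed + 20 + i, edgeShiftMm = shift,
                          meta = meta)
      raw <- .toRawImage(ke$image, p$responseCoeffs, p$edgeNoiseSdRaw,
                         seed = seed + 40 + i)
      linearize(raw, model)
    })
    estimateEmtf(edges, edgeConfig, geometry)
  })

  # -- flat-field eNNPS ------------------------------------------------
  ennpsCurve <- .runStage("ennps", {
    n <- nnpsConfig@roiPx + 8
    flats <- lapply(seq_len(nnpsConfig@nImages), function(i) {
      ff <- makeFlatField(p$flatKermaUGy, 0, pitch, c(n, n),
                          seed = seed + 60 + i, meta = meta)
      raw <- .toRawImage(ff$image, p$responseCoeffs, p$flatNoiseSdRaw,
                         seed = seed + 80 + i)
      linearize(raw, model)
    })
    nnps1dVertical(nnps2d(flats, nnpsConfig), nnpsConfig, geometry)
  })

  # -- beam-stop scatter fraction --------------------------------------
  scatter <- .runStage("scatter_dose", {
    gridSp <- p$grid
    extent <- (max(gridSp@nRows, gridSp@nCols) - 1) * gridSp@pitchMm +
      gridSp@cylinderDiameterMm
    n <- ceiling(extent / pitch) + 32
    primary <- p$flatKermaUGy * (1 - p$sf)
    scatterLvl <- p$flatKermaUGy * p$sf
    bs <- makeBeamStopImage(gridSp, primary, scatterLvl,
                            leadTransmission = 0,
                            noiseSd = 0, pitchMm = pitch, shape = c(n, n),
                            seed = seed + 100, meta = meta)
    raw <- .toRawImage(bs$image, p$responseCoeffs, p$beamstopNoiseSd,
                       seed = seed + 101)
    measureScatterFraction(linearize(raw, model), gridSp)
  })

  # -- dose geometry ---------------------------------------------------
  doseVals <- .runStage("scatter_dose", {
    readings <- DoseReadings(p$tf * p$akWithoutUGy, p$akWithoutUGy,
                             sddCm = p$sddCm, sidCm = p$sidCm,
                             beamMode = p$beamMode)
    tf <- transmissionFactor(readings)
    iak <- incidentAirKerma(readings@akWithoutPhantomUGy, readings)
    list(tf = tf, iak = iak, dak = detectorAirKerma(iak, tf))
  })

  # -- photon fluence per air kerma ------------------------------------
  qv <- .runStage("fluence", {
    if (!is.null(p$qOverride)) {
      list(q = p$qOverride, phiTot = NA_real_, akUGy = NA_real_)
    } else {
      if (is.null(p$kvp)) stopf('missing "q": supply qOverride or kvp/filtration')
      qValue(makeSpectrum(p$kvp, p$filtrAl, p$filtrCu))
    }
  })

  # -- composition -----------------------------------------------------
  out <- .runStage("metrics", {
    curves <- resampleCommonGrid(list(emtfCurve, ennpsCurve),
                                 step = gridStep, fmax = fmax)
    m <- SystemMeasurement(curves[[1]], curves[[2]], sf = scatter@sf,
                           tf = doseVals$tf, akUGy = doseVals$iak,
                           qPerUGyMm2 = qv$q, meta = meta)
    list(measurement = m, eneq = eneq(m), edqe = edqe(m))
  })
  pkNeq <- maxPeak(out$eneq)
  pkDqe <- maxPeak(out$edqe)
  summary <- c(TF = doseVals$tf, q = qv$q, SF = scatter@sf,
               AK = doseVals$iak, DAK = doseVals$dak,
               maxENEQ = unname(pkNeq["value"]),
               maxEDQE = unname(pkDqe["value"]))
  list(measurement = out$measurement, edqe = out$edqe, eneq = out$eneq,
       response = model, scatter = scatter, summary = summary,
       params = p)
}

#' Run a full synthetic multi-system protocol
#'
#' Simulates and measures every configured system under one protocol,
#' composes the eNEQ and eDQE curves, and runs the stratified rank-based
#' comparison across systems for both metrics. Reproducible from
#' (configuration, seed) alone.
#'
#' @param systems named list of parameter lists (defaults: the three
#'   systems of \code{\link{syntheticSystemDefaults}} under the chest
#'   protocol).
#' @param seed integer master seed; each system derives its own stream.
#' @param protocol protocol used for the default system set.
#' @param edgeConfig,nnpsConfig,gridStep,fmax passed to
#'   \code{\link{measureSyntheticSystem}}.
#' @param outDir optional directory; when given, curves (CSV), summaries
#'   and a manifest (JSON) are written there.
#' @return list with per-system results (\code{systems}), comparison
#'   reports (\code{reports$eDQE}, \code{reports$eNEQ}), a summary table
#'   (\code{summary}) and the run \code{manifest}.
#' @export
runProtocol <- function(systems = NULL, seed = 1, protocol = "chest",
                        edgeConfig = EdgeAnalysisConfig(roiSizeMm = 50),
                        nnpsConfig = NnpsConfig(roiPx = 512),
                        gridStep = 0.1, fmax = NULL, outDir = NULL) {
  if (is.null(systems)) {
    systems <- list(
      ldss = syntheticSystemDefaults("ldss", protocol),
      dr1 = syntheticSystemDefaults("dr1", protocol),
      dr2 = syntheticSystemDefaults("dr2", protocol)
    )
  }
  results <- list()
  for (i in seq_along(systems)) {
    results[[names(systems)[i]]] <- measureSyntheticSystem(
      systems[[i]], seed = seed + 1000 * i, edgeConfig = edgeConfig,
      nnpsConfig = nnpsConfig, gridStep = gridStep, fmax = fmax)
  }
  # common grid for the comparison: truncate to the shortest curve
  fcommon <- min(vapply(results, function(r) max(frequencies(r$edqe)),
                        numeric(1)))
  trim <- function(cv) {
    keep <- frequencies(cv) <= fcommon + 1e-9
    FrequencySeries(frequencies(cv)[keep], seriesValues(cv)[keep],
                    plane = plane(cv), quantity = quantity(cv))
  }
  edqeCurves <- lapply(results, function(r) trim(r$edqe))
  eneqCurves <- lapply(results, function(r) trim(r$eneq))
  reports <- list(
    eDQE = pairwiseReport(edqeCurves, FreqBinSpec("eDQE")),
    eNEQ = pairwiseReport(eneqCurves, FreqBinSpec("eNEQ"))
  )
  summaryTab <- do.call(rbind, lapply(results, function(r)
    as.data.frame(as.list(r$summary))))
  summaryTab <- cbind(system = names(results), summaryTab)
  rownames(summaryTab) <- NULL
  manifest <- list(
    package = "effiq",
    version = as.character(utils::packageVersion("effiq")),
    seed = seed, protocol = protocol,
    systems = names(systems),
    gridStep = gridStep,
    nnps = list(roiPx = nnpsConfig@roiPx, subPx = nnpsConfig@subPx,
                overlapPx = nnpsConfig@overlapPx),
    edge = list(roiSizeMm = edgeConfig@roiSizeMm,
                window = edgeConfig@window)
  )
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      writeSeries(results[[nm]]$edqe, file.path(outDir, paste0(nm, "_edqe.csv")))
      writeSeries(results[[nm]]$eneq, file.path(outDir, paste0(nm, "_eneq.csv")))
    }
    utils::write.csv(summaryTab, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(systems = results, reports = reports, summary = summaryTab,
       manifest = manifest)
}
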