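## Accessor generics and show methods.

#' Photon counts of a line-scan stack
#' @param object a \linkS4class{SpectralLineScanStack}.
#' @return integer array [nLines, nPixels, nChannels].
#' @export
setGeneric("photonCounts", function(object) standardGeneric("photonCounts"))

#' @rdname photonCounts
#' @export
setMethod("photonCounts", "SpectralLineScanStack",
          function(object) object@counts)

#' Scan geometry accessor
#' @param object an object carrying a \linkS4class{ScanGeometry}.
#' @return the \linkS4class{ScanGeometry}.
#' @export
setGeneric("scanGeometry", function(object) standardGeneric("scanGeometry"))

#' @rdname scanGeometry
#' @export
setMethod("scanGeometry", "SpectralLineScanStack",
          function(object) object@geometry)

#' Channel wavelength bounds accessor
#' @param object an object with spectral channels.
#' @return two-column matrix of bounds (nm).
#' @export
setGeneric("channelBounds", function(object) standardGeneric("channelBounds"))

#' @rdname channelBounds
#' @export
setMethod("channelBounds", "SpectralLineScanStack",
          function(object) object@channelBounds)

#' @rdname channelBounds
#' @export
setMethod("channelBounds", "EmissionSpectrum",
          function(object) object@channelBounds)

#' Filter weight matrix accessor
#' @param object a \linkS4class{SpectralFilterSet}.
#' @return matrix [nSpecies, nChannels].
#' @export
setGeneric("filterMatrix", function(object) standardGeneric("filterMatrix"))

#' @rdname filterMatrix
#' @export
setMethod("filterMatrix", "SpectralFilterSet", function(object) object@filters)

#' Lag times accessor
#' @param object a correlation curve or surface.
#' @return numeric vector of lag times (s).
#' @export
setGeneric("lagTimes", function(object) standardGeneric("lagTimes"))

#' @rdname lagTimes
#' @export
setMethod("lagTimes", "CorrelationCurve", function(object) object@lagTimes)

#' @rdname lagTimes
#' @export
setMethod("lagTimes", "CorrelationSurface", function(object) object@lagTimes)

#' Correlation amplitudes accessor
#' @param object a correlation curve or surface.
#' @return numeric vector (curve) or matrix (surface) of G values.
#' @export
setGeneric("corrValues", function(object) standardGeneric("corrValues"))

#' @rdname corrValues
#' @export
setMethod("corrValues", "CorrelationCurve", function(object) object@G)

#' @rdname corrValues
#' @export
setMethod("corrValues", "CorrelationSurface", function(object) object@G)

#' Beam waist accessor
#' @param object an object carrying a beam-waist estimate.
#' @return waist in micrometres.
#' @export
setGeneric("beamWaist", function(object) standardGeneric("beamWaist"))

#' @rdname beamWaist
#' @export
setMethod("beamWaist", "PSFModel", function(object) object@waist)

#' @rdname beamWaist
#' @export
setMethod("beamWaist", "CorrelationSurface", function(object) object@waist)

#' @rdname beamWaist
#' @export
setMethod("beamWaist", "DiffusionFitResult", function(object) object@waist)

#' @rdname beamWaist
#' @export
setMethod("beamWaist", "TransitionTimeResult", function(object) object@waist)

#' Diffusion coefficient accessor
#' @param object a diffusion estimate.
#' @return D in um^2/s (vector for multi-species fits).
#' @export
setGeneric("diffusionCoef", function(object) standardGeneric("diffusionCoef"))

#' @rdname diffusionCoef
#' @export
setMethod("diffusionCoef", "DiffusionFitResult", function(object) object@D)

#' @rdname diffusionCoef
#' @export
setMethod("diffusionCoef", "TransitionTimeResult", function(object) object@D)

#' Movie frames accessor
#' @param object a \linkS4class{TimeLapseStack}.
#' @return numeric array [nFrames, height, width, nChannels].
#' @export
setGeneric("movieFrames", function(object) standardGeneric("movieFrames"))

#' @rdname movieFrames
#' @export
setMethod("movieFrames", "TimeLapseStack", function(object) object@frames)

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf(
    "ScanGeometry: %d px x %.3f um (%.1f nm/px), dwell %.2f us,\n  line period %.0f us, %d lines, %s\n",
    object@nPixels, object@lineLength, object@pixelSize * 1e3,
    object@pixelDwell * 1e6, object@linePeriod * 1e6, object@nLines,
    if (object@bidirectional) "bidirectional" else "unidirectional"))
})

setMethod("show", "SpectralLineScanStack", function(object) {
  d <- dim(object@counts)
  cat(sprintf("SpectralLineScanStack: %d lines x %d pixels x %d channels\n",
              d[1], d[2], d[3]))
  cat(sprintf("  mean counts/dwell: %.4f; reordered: %s\n",
              mean(object@counts), object@reordered))
  show(object@geometry)
})

setMethod("show", "SpectralFilterSet", function(object) {
  cat(sprintf("SpectralFilterSet: %d species x %d channels\n",
              nrow(object@filters), ncol(object@filters)))
  cat("  species:", paste(object@species, collapse = ", "), "\n")
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve [%s x %s]: %d lags, %.3g .. %.3g s\n",
              object@species[1], object@species[2], length(object@lagTimes),
              min(object@lagTimes), max(object@lagTimes)))
  cat(sprintf("  G(min lag) = %.4g\n", object@G[1]))
})

setMethod("show", "CorrelationSurface", function(object) {
  cat(sprintf(
    "CorrelationSurface: %d temporal x %d spatial lags; waist %.3f um (segment %s)\n",
    length(object@lagTimes), length(object@spatialLags), object@waist,
    object@segment))
})

setMethod("show", "DiffusionFitResult", function(object) {
  cat(sprintf("DiffusionFitResult: %d species, waist %.3f um\n",
              object@nSpecies, object@waist))
  for (i in seq_len(object@nSpecies))
    cat(sprintf("  D%d = %.4g um^2/s, A%d = %.4g\n", i, object@D[i], i,
                object@amplitudes[i]))
  cat(sprintf("  offset = %.4g, residual RMS = %.4g\n", object@offset,
              object@residualRms))
})

setMethod("show", "TransitionTimeResult", function(object) {
  cat(sprintf(
    "TransitionTimeResult: G0 = %.4g, gammaD = %.4g s, D = %.4g um^2/s (w = %.3f um)\n",
    object@G0, object@gammaD, object@D, object@waist))
})

setMethod("show", "SegmentDiffusionProfile", function(object) {
  cat(sprintf(
    "SegmentDiffusionProfile: %d segments (%d excluded), cor(D, partner) = %.3f\n",
    length(object@position), object@excluded, object@correlation))
})

setMethod("show", "RadialCellMask", function(object) {
  cat(sprintf(
    "RadialCellMask: footprint %d px, membrane %d px, cytosol %d px (boundary %.2f)\n",
    sum(object@footprint), sum(object@membrane), sum(object@cytosol),
    object@boundary))
})

setMethod("show", "TimeLapseStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "TimeLapseStack: %d frames x %d x %d px x %d channels, dt = %.3g s\n",
    d[1], d[2], d[3], d[4], object@frameInterval))
})
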