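#' @import methods
#' @importFrom stats coef cor median predict rnorm rpois runif sd
#'   smooth.spline var vcov
#' @importFrom utils read.delim write.table packageVersion
#' @useDynLib lineFSCS, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## Scan geometry
## ---------------------------------------------------------------------------

#' Line-scan acquisition geometry
#'
#' Describes a one-dimensional bidirectional (or unidirectional) scanned
#' acquisition: a line of \code{nPixels} pixels of size \code{pixelSize}
#' (micrometres) swept every \code{linePeriod} seconds, each pixel dwelling
#' \code{pixelDwell} seconds under the beam, repeated for \code{nLines}
#' sweeps.
#'
#' @slot lineLength numeric, scan length in micrometres.
#' @slot nPixels integer, pixels per line.
#' @slot pixelSize numeric, pixel pitch in micrometres.
#' @slot pixelDwell numeric, dwell time per pixel in seconds.
#' @slot linePeriod numeric, time between successive line starts in seconds.
#' @slot nLines integer, number of lines acquired.
#' @slot bidirectional logical, whether odd lines are scanned in reverse.
#' @export
setClass("ScanGeometry",
  representation(lineLength = "numeric", nPixels = "integer",
                 pixelSize = "numeric", pixelDwell = "numeric",
                 linePeriod = "numeric", nLines = "integer",
                 bidirectional = "logical"),
  validity = function(object) {
    msg <- character()
    vals <- c(object@lineLength, object@nPixels, object@pixelSize,
              object@pixelDwell, object@linePeriod, object@nLines)
    if (any(!is.finite(vals)) || any(vals <= 0))
      msg <- c(msg, "all geometry scalars must be positive and finite")
    else {
      if (abs(object@nPixels * object@pixelSize - object@lineLength) >
          0.01 * object@lineLength)
        msg <- c(msg, "nPixels * pixelSize must equal lineLength within 1%")
      if (object@nPixels * object@pixelDwell > object@linePeriod * (1 + 1e-9))
        msg <- c(msg, "nPixels * pixelDwell must not exceed linePeriod")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a ScanGeometry
#'
#' Defaults reproduce the acquisition used throughout: 256 pixels of
#' 21 nm over a 5.355 um line, 0.51 us pixel dwell, 154 us line period,
#' bidirectional scanning.  \code{nLines} defaults to 50,000 (a
#' desk-scale record; full acquisitions use 300,000).
#'
#' @param lineLength scan length, micrometres.
#' @param nPixels pixels per line.
#' @param pixelSize pixel pitch, micrometres.
#' @param pixelDwell seconds per pixel.
#' @param linePeriod seconds per line.
#' @param nLines number of lines.
#' @param bidirectional logical.
#' @return A \linkS4class{ScanGeometry}.
#' @export
ScanGeometry <- function(lineLength = 5.355, nPixels = 256L,
                         pixelSize = 0.021, pixelDwell = 0.51e-6,
                         linePeriod = 154e-6, nLines = 50000L,
                         bidirectional = TRUE) {
  new("ScanGeometry", lineLength = lineLength,
      nPixels = as.integer(nPixels), pixelSize = pixelSize,
      pixelDwell = pixelDwell, linePeriod = linePeriod,
      nLines = as.integer(nLines), bidirectional = bidirectional)
}

## ---------------------------------------------------------------------------
## Emission spectra and species
## ---------------------------------------------------------------------------

#' Discrete emission spectrum over detector channels
#'
#' The probability that a detected photon of one species falls into each
#' spectral channel, after all filters/dichroics in the detection path.
#'
#' @slot channelBounds two-column matrix of channel wavelength bounds (nm),
#'   ascending and non-overlapping.
#' @slot probabilities per-channel detection probabilities; nonnegative,
#'   summing to one.
#' @export
setClass("EmissionSpectrum",
  representation(channelBounds = "matrix", probabilities = "numeric"),
  validity = function(object) {
    msg <- character()
    p <- object@probabilities
    b <- object@channelBounds
    if (ncol(b) != 2L) msg <- c(msg, "channelBounds must have two columns")
    else {
      if (nrow(b) != length(p))
        msg <- c(msg, "one probability per channel required")
      if (any(b[, 2] <= b[, 1]))
        msg <- c(msg, "channel upper bounds must exceed lower bounds")
      if (nrow(b) > 1 && any(b[-1, 1] < b[-nrow(b), 2]))
        msg <- c(msg, "channel bounds must be ascending and non-overlapping")
    }
    if (any(p < 0)) msg <- c(msg, "probabilities must be nonnegative")
    if (abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, "probabilities must sum to 1 within 1e-9")
    if (length(msg)) msg else TRUE
  })

#' Construct an EmissionSpectrum
#'
#' @param channelBounds two-column matrix (nm) or a numeric vector of
#'   breakpoints from which contiguous channels are formed.
#' @param probabilities per-channel probabilities; normalized to sum to 1.
#' @return An \linkS4class{EmissionSpectrum}.
#' @export
EmissionSpectrum <- function(channelBounds, probabilities) {
  if (is.numeric(channelBounds) && is.null(dim(channelBounds)))
    channelBounds <- cbind(channelBounds[-length(channelBounds)],
                           channelBounds[-1])
  s <- sum(probabilities)
  if (s <= 0) stop("probabilities must have a positive sum")
  new("EmissionSpectrum", channelBounds = channelBounds,
      probabilities = probabilities / s)
}

#' Fluorescent species specification for the photon-stream simulator
#'
#' @slot label species name.
#' @slot D diffusion coefficient, um^2/s (0 only for immobile species).
#' @slot brightness mean detected counts per pixel dwell for a molecule at
#'   the beam centre.
#' @slot density molecules per um^2 in the simulation box.
#' @slot spectrum an \linkS4class{EmissionSpectrum}.
#' @slot mobile logical; immobile species stay fixed (e.g. stable clusters).
#' @export
setClass("SpeciesSpec",
  representation(label = "character", D = "numeric", brightness = "numeric",
                 density = "numeric", spectrum = "EmissionSpectrum",
                 mobile = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@D < 0) msg <- c(msg, "D must be >= 0")
    if (object@D == 0 && object@mobile)
      msg <- c(msg, "mobile species must have D > 0")
    if (object@brightness < 0) msg <- c(msg, "brightness must be >= 0")
    if (object@density <= 0) msg <- c(msg, "density must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a SpeciesSpec
#'
#' @param label species name.
#' @param D diffusion coefficient, um^2/s.
#' @param brightness counts per dwell at beam centre.
#' @param density molecules per um^2.
#' @param spectrum an \linkS4class{EmissionSpectrum}.
#' @param mobile logical.
#' @return A \linkS4class{SpeciesSpec}.
#' @export
SpeciesSpec <- function(label, D, brightness, density, spectrum,
                        mobile = TRUE) {
  new("SpeciesSpec", label = label, D = D, brightness = brightness,
      density = density, spectrum = spectrum, mobile = mobile)
}

#' Gaussian detection-profile model
#'
#' @slot waist numeric, 1/e^2 radius of the Gaussian detection profile
#'   (micrometres).
#' @export
setClass("PSFModel", representation(waist = "numeric"),
  validity = function(object)
    if (object@waist <= 0) "waist must be positive" else TRUE)

#' Construct a PSFModel
#' @param waist 1/e^2 beam radius in micrometres.
#' @return A \linkS4class{PSFModel}.
#' @export
PSFModel <- function(waist = 0.25) new("PSFModel", waist = waist)

## ---------------------------------------------------------------------------
## Line-scan photon-count stack
## ---------------------------------------------------------------------------

#' Spectrally resolved line-scan photon-count stack
#'
#' 8-bit photon counts per (line, pixel, spectral channel), plus the scan
#' geometry and channel wavelength bounds.  The raw-data object of
#' line-scanning FSCS.
#'
#' @slot counts integer array [nLines, nPixels, nChannels], values 0..255.
#' @slot geometry a \linkS4class{ScanGeometry}.
#' @slot channelBounds two-column matrix of channel bounds (nm).
#' @slot provenance list of free-form metadata (seed, ground truth, ...).
#' @slot reordered logical; TRUE once bidirectional lines have been
#'   rewritten into a common spatial orientation.
#' @export
setClass("SpectralLineScanStack",
  representation(counts = "array", geometry = "ScanGeometry",
                 channelBounds = "matrix", provenance = "list",
                 reordered = "logical"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@counts)
    if (length(d) != 3L)
      msg <- c(msg, "counts must be a 3D [line, pixel, channel] array")
    else {
      if (d[1] != object@geometry@nLines || d[2] != object@geometry@nPixels)
        msg <- c(msg, "counts dimensions disagree with geometry")
      if (d[3] != nrow(object@channelBounds))
        msg <- c(msg, "counts channel dimension disagrees with channelBounds")
    }
    rng <- suppressWarnings(range(object@counts))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 255))
      msg <- c(msg, "counts must lie in 0..255")
    if (length(msg)) msg else TRUE
  })

#' Construct a SpectralLineScanStack
#' @param counts integer array [nLines, nPixels, nChannels].
#' @param geometry a \linkS4class{ScanGeometry}.
#' @param channelBounds two-column matrix (nm).
#' @param provenance metadata list.
#' @param reordered logical.
#' @return A \linkS4class{SpectralLineScanStack}.
#' @export
SpectralLineScanStack <- function(counts, geometry, channelBounds,
                                  provenance = list(), reordered = FALSE) {
  storage.mode(counts) <- "integer"
  new("SpectralLineScanStack", counts = counts, geometry = geometry,
      channelBounds = channelBounds, provenance = provenance,
      reordered = reordered)
}

## ---------------------------------------------------------------------------
## Time-lapse image stack
## ---------------------------------------------------------------------------

#' Multi-channel time-lapse image stack
#'
#' @slot frames numeric array [nFrames, height, width, nChannels],
#'   nonnegative intensities.
#' @slot frameInterval numeric, seconds between frames.
#' @slot channelNames character vector of channel labels.
#' @export
setClass("TimeLapseStack",
  representation(frames = "array", frameInterval = "numeric",
                 channelNames = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@frames)
    if (length(d) != 4L)
      msg <- c(msg, "frames must be [frame, y, x, channel]")
    else if (d[4] != length(object@channelNames))
      msg <- c(msg, "one channel name per channel required")
    if (any(object@frames < 0))
      msg <- c(msg, "intensities must be nonnegative")
    if (object@frameInterval <= 0)
      msg <- c(msg, "frameInterval must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a TimeLapseStack
#' @param frames numeric array [nFrames, height, width, nChannels].
#' @param frameInterval seconds between frames.
#' @param channelNames channel labels (defaults to ch1..chC).
#' @return A \linkS4class{TimeLapseStack}.
#' @export
TimeLapseStack <- function(frames, frameInterval = 1,
                           channelNames = NULL) {
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(frames)[4]))
  new("TimeLapseStack", frames = frames, frameInterval = frameInterval,
      channelNames = channelNames)
}

## ---------------------------------------------------------------------------
## Spectral filters
## ---------------------------------------------------------------------------

#' Statistical spectral filter set
#'
#' Per-species weight vectors over spectral channels that decompose
#' multi-channel photon counts into species-specific contributions.
#' Computed by weighted least squares from normalized reference spectra
#' and the mixed sample spectrum; when the mixed spectrum is an exact
#' nonnegative combination of the references the filters of all species
#' sum to one in every channel.
#'
#' @slot filters matrix [nSpecies, nChannels] of filter weights.
#' @slot species character labels.
#' @slot references matrix [nChannels, nSpecies] of normalized reference
#'   spectra.
#' @slot mixed numeric, the per-channel mean intensity the filters were
#'   computed from.
#' @export
setClass("SpectralFilterSet",
  representation(filters = "matrix", species = "character",
                 references = "matrix", mixed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@filters) != length(object@species))
      msg <- c(msg, "one filter row per species required")
    if (ncol(object@filters) != nrow(object@references))
      msg <- c(msg, "filters and references disagree on channel count")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Correlation results
## ---------------------------------------------------------------------------

#' Temporal correlation curve
#'
#' Fluctuation correlation G(tau) (the raw normalized correlation minus
#' one) on a quasi-logarithmic multi-tau lag grid.
#'
#' @slot lagTimes numeric, lag times in seconds, strictly increasing.
#' @slot G numeric, correlation amplitudes.
#' @slot nSamples numeric, products/samples contributing per lag.
#' @slot species character of length 2: the species pair correlated.
#' @export
setClass("CorrelationCurve",
  representation(lagTimes = "numeric", G = "numeric", nSamples = "numeric",
                 species = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@lagTimes) != length(object@G))
      msg <- c(msg, "lagTimes and G must have equal length")
    if (any(diff(object@lagTimes) <= 0))
      msg <- c(msg, "lag grid must be strictly increasing")
    if (length(object@nSamples) && any(object@nSamples <= 0))
      msg <- c(msg, "samples per lag must be positive")
    if (length(msg)) msg else TRUE
  })

#' Spatio-temporal correlation surface
#'
#' G(t, delta) over temporal lags t and spatial lags delta, with the beam
#' waist recovered from the spatial cross-correlation profile.
#'
#' @slot lagTimes numeric, temporal lags in seconds.
#' @slot spatialLags numeric, spatial lags in micrometres (including 0).
#' @slot G matrix [nLags, nDeltas].
#' @slot nSamples numeric, samples per temporal lag.
#' @slot waist numeric, beam waist estimate (um).
#' @slot waistSe numeric, its standard error.
#' @slot segment character, segment index or "line-average".
#' @export
setClass("CorrelationSurface",
  representation(lagTimes = "numeric", spatialLags = "numeric",
                 G = "matrix", nSamples = "numeric", waist = "numeric",
                 waistSe = "numeric", segment = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@G) != length(object@lagTimes) ||
        ncol(object@G) != length(object@spatialLags))
      msg <- c(msg, "G dimensions must match lag grids")
    if (length(object@waist) && object@waist <= 0)
      msg <- c(msg, "waist must be positive")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Diffusion results
## ---------------------------------------------------------------------------

#' n-species 2D free-diffusion fit result
#'
#' @slot offset numeric, baseline G_offset.
#' @slot amplitudes numeric, per-species amplitudes A_i.
#' @slot D numeric, per-species diffusion coefficients (um^2/s),
#'   ascending.
#' @slot waist numeric, beam waist held fixed during the fit (um).
#' @slot residualRms numeric, root-mean-square residual.
#' @slot se list of parameter standard errors.
#' @slot nSpecies integer.
#' @export
setClass("DiffusionFitResult",
  representation(offset = "numeric", amplitudes = "numeric", D = "numeric",
                 waist = "numeric", residualRms = "numeric", se = "list",
                 nSpecies = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@D <= 0)) msg <- c(msg, "fitted D must be positive")
    if (is.unsorted(object@D))
      msg <- c(msg, "species must be reported in ascending D order")
    if (length(msg)) msg else TRUE
  })

#' Fitting-free transition-time result
#'
#' @slot G0 numeric, zero-lag amplitude extrapolated by spline smoothing.
#' @slot gammaD numeric, lag at which the smoothed curve falls to G0/2 (s).
#' @slot D numeric, w^2 / (4 gammaD), um^2/s.
#' @slot waist numeric, beam waist used (um).
#' @slot spar numeric, smoothing parameter used.
#' @export
setClass("TransitionTimeResult",
  representation(G0 = "numeric", gammaD = "numeric", D = "numeric",
                 waist = "numeric", spar = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@gammaD <= 0) msg <- c(msg, "gammaD must be positive")
    if (abs(object@D - object@waist^2 / (4 * object@gammaD)) >
        1e-12 * max(1, object@D))
      msg <- c(msg, "D must equal waist^2/(4 gammaD)")
    if (length(msg)) msg else TRUE
  })

#' Per-segment diffusion vs partner-intensity profile
#'
#' @slot position numeric, segment centre positions along the line (um).
#' @slot D numeric, per-segment fitting-free diffusion coefficients;
#'   NA where the segment curve did not decay.
#' @slot partnerIntensity numeric, per-segment mean filtered intensity of
#'   the partner species (counts/dwell).
#' @slot correlation numeric, Pearson correlation of D and partner
#'   intensity across usable segments.
#' @slot excluded integer, number of segments excluded.
#' @export
setClass("SegmentDiffusionProfile",
  representation(position = "numeric", D = "numeric",
                 partnerIntensity = "numeric", correlation = "numeric",
                 excluded = "integer"),
  validity = function(object) {
    msg <- character()
    n <- length(object@position)
    if (length(object@D) != n || length(object@partnerIntensity) != n)
      msg <- c(msg, "profile vectors must have equal length")
    if (length(object@correlation) == 1 && !is.na(object@correlation) &&
        abs(object@correlation) > 1 + 1e-12)
      msg <- c(msg, "correlation must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Radial cell mask
## ---------------------------------------------------------------------------

#' Radial membrane/cytosol partition of a cell footprint
#'
#' Each footprint pixel carries a normalized radial coordinate (0 at the
#' centre of mass, 1 at the detected edge); the footprint is partitioned
#' into a peripheral membrane shell and a cytosol core.
#'
#' @slot footprint logical matrix, the cell footprint.
#' @slot radial numeric matrix, normalized radial coordinate (NA outside).
#' @slot membrane logical matrix.
#' @slot cytosol logical matrix.
#' @slot boundary numeric, shell boundary parameter in [0, 1].
#' @export
setClass("RadialCellMask",
  representation(footprint = "matrix", radial = "matrix",
                 membrane = "matrix", cytosol = "matrix",
                 boundary = "numeric"),
  validity = function(object) {
    msg <- character()
    fp <- object@footprint
    if (!identical(dim(fp), dim(object@membrane)) ||
        !identical(dim(fp), dim(object@cytosol)))
      msg <- c(msg, "all masks must share the footprint dimensions")
    else {
      if (any(object@membrane & object@cytosol))
        msg <- c(msg, "membrane and cytosol must be disjoint")
      if (!all((object@membrane | object@cytosol) == fp))
        msg <- c(msg, "membrane and cytosol must partition the footprint")
      r <- object@radial[fp]
      if (any(is.na(r)) || any(r < -1e-9) || any(r > 1 + 1e-9))
        msg <- c(msg, "radial coordinate must lie in [0, 1] on the footprint")
    }
    if (length(msg)) msg else TRUE
  })

#' Membrane translocation trace
#'
#' @slot ratio numeric, per-frame membrane/cytosol mean-intensity ratio.
#' @slot foldChange numeric, ratio normalized to the mean of the first
#'   four frames.
#' @slot channel character, channel label.
#' @export
setClass("TranslocationTrace",
  representation(ratio = "numeric", foldChange = "numeric",
                 channel = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@ratio < 0)) msg <- c(msg, "ratios must be nonnegative")
    if (length(object@foldChange) >= 4 &&
        abs(mean(object@foldChange[1:4]) - 1) > 1e-9)
      msg <- c(msg, "fold-change must average to 1 over frames 1-4")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Cell-movie specification
## ---------------------------------------------------------------------------

#' Synthetic cell-movie specification
#'
#' Describes an elliptical cell on a dark background whose per-channel
#' intensity is split between a peripheral membrane shell and the cytosol
#' core according to a per-frame membrane fraction, with optional
#' punctate clusters appearing at an onset frame, under Poisson photon
#' noise and additive Gaussian read noise.
#'
#' @slot imageShape integer of length 2, (height, width) in pixels.
#' @slot frameInterval numeric, seconds.
#' @slot nFrames integer.
#' @slot center numeric of length 2, cell centre (y, x) in pixels.
#' @slot radii numeric of length 2, ellipse radii (y, x) in pixels.
#' @slot shellFraction numeric in (0, 1): the outer fraction of the
#'   normalized radius that counts as membrane.
#' @slot channels list of per-channel specs; each a list with fields
#'   \code{label}, \code{totalIntensity} (scalar or per-frame),
#'   \code{membraneFraction} (scalar or per-frame), \code{nClusters},
#'   \code{clusterRadius}, \code{clusterAmplitude}, \code{onsetFrame}
#'   (NA for no clusters).
#' @slot photonScale numeric, photons per intensity unit for Poisson
#'   noise (0 disables).
#' @slot gaussianSd numeric, additive Gaussian noise sd (0 disables).
#' @export
setClass("CellMovieSpec",
  representation(imageShape = "integer", frameInterval = "numeric",
                 nFrames = "integer", center = "numeric", radii = "numeric",
                 shellFraction = "numeric", channels = "list",
                 photonScale = "numeric", gaussianSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@shellFraction <= 0 || object@shellFraction >= 1)
      msg <- c(msg, "shellFraction must lie strictly inside (0, 1)")
    ys <- object@center[1]; xs <- object@center[2]
    if (ys - object@radii[1] < 1 || ys + object@radii[1] > object@imageShape[1] ||
        xs - object@radii[2] < 1 || xs + object@radii[2] > object@imageShape[2])
      msg <- c(msg, "cell must lie fully inside the frame")
    for (ch in object@channels) {
      mf <- ch$membraneFraction
      if (any(mf < 0) || any(mf > 1))
        msg <- c(msg, "membrane fractions must lie in [0, 1]")
      if (!is.na(ch$onsetFrame) && ch$onsetFrame >= object@nFrames)
        msg <- c(msg, "onset frame must be smaller than nFrames")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a CellMovieSpec
#'
#' @param imageShape (height, width) in pixels.
#' @param frameInterval seconds between frames.
#' @param nFrames number of frames.
#' @param center cell centre (y, x).
#' @param radii ellipse radii (y, x).
#' @param shellFraction outer membrane shell fraction of the normalized
#'   radius, in (0, 1).
#' @param channels list of channel specs; see \linkS4class{CellMovieSpec}.
#' @param photonScale photons per intensity unit (0 = no Poisson noise).
#' @param gaussianSd additive Gaussian noise sd (0 = none).
#' @return A \linkS4class{CellMovieSpec}.
#' @export
CellMovieSpec <- function(imageShape = c(64L, 64L), frameInterval = 1,
                          nFrames = 20L, center = imageShape / 2,
                          radii = c(20, 24), shellFraction = 0.25,
                          channels = list(cellChannel()),
                          photonScale = 0, gaussianSd = 0) {
  channels <- lapply(channels, function(ch) {
    ch$totalIntensity <- rep_len(ch$totalIntensity, nFrames)
    ch$membraneFraction <- rep_len(ch$membraneFraction, nFrames)
    ch
  })
  new("CellMovieSpec", imageShape = as.integer(imageShape),
      frameInterval = frameInterval, nFrames = as.integer(nFrames),
      center = as.numeric(center), radii = as.numeric(radii),
      shellFraction = shellFraction, channels = channels,
      photonScale = photonScale, gaussianSd = gaussianSd)
}

#' Per-channel spec for a synthetic cell movie
#'
#' @param label channel label.
#' @param totalIntensity total cell intensity per frame (scalar or vector).
#' @param membraneFraction fraction of intensity in the membrane shell
#'   (scalar or per-frame vector).
#' @param nClusters number of punctate clusters (0 for none).
#' @param clusterRadius cluster radius, pixels.
#' @param clusterAmplitude added intensity per cluster pixel.
#' @param onsetFrame first frame at which clusters appear (NA = never).
#' @return A list usable in \code{CellMovieSpec(channels = ...)}.
#' @export
cellChannel <- function(label = "ch1", totalIntensity = 1e4,
                        membraneFraction = 0.5, nClusters = 0L,
                        clusterRadius = 2, clusterAmplitude = 0,
                        onsetFrame = NA_integer_) {
  list(label = label, totalIntensity = totalIntensity,
       membraneFraction = membraneFraction, nClusters = as.integer(nClusters),
       clusterRadius = clusterRadius, clusterAmplitude = clusterAmplitude,
       onsetFrame = onsetFrame)
}
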