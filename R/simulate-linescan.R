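## Synthetic photon-stream generator for line-scan FSCS.

#' Simulate a spectrally resolved line-scan photon stream
#'
#' Generates the photon-count stack a scanned Gaussian beam would record
#' over a membrane carrying the given fluorescent species.  Mobile
#' species perform 2D Brownian motion (step variance 2 D dt per axis per
#' line period) in a periodic box centred on the scan line; immobile
#' species stay fixed.  The detected rate per pixel dwell is the sum
#' over molecules of \code{brightness * exp(-2 r^2 / w^2)}, with r the
#' molecule-to-beam distance at that pixel.  Counts are Poisson draws
#' split multinomially over spectral channels by each species' emission
#' spectrum, summed over species, and clipped at 255 (the 8-bit
#' detector range).  When the geometry is bidirectional, odd-numbered
#' lines are written in reversed pixel order, as acquired.
#'
#' Molecule positions are updated once per line period: the pixel dwell
#' (0.51 us) is ~300x shorter than the line period (154 us), so
#' intra-line motion is negligible at membrane-protein diffusion
#' coefficients.
#'
#' The single seed is expanded into independent per-species substreams
#' (recorded in the provenance), so adding a species never perturbs the
#' photon stream of the others.
#'
#' @param species a \linkS4class{SpeciesSpec} or list of them; all must
#'   share one channel layout.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @param psf a \linkS4class{PSFModel}.
#' @param boxSize numeric of length 2: periodic box (x, y) in
#'   micrometres; must exceed the line length in x.
#' @param seed integer seed.
#' @param keepTotals logical; if TRUE the pre-split (and pre-clip)
#'   per-dwell Poisson totals are stored in the provenance (memory
#'   intensive; intended for small validation stacks).
#' @param trackFirst logical; if TRUE the per-line trajectory of the
#'   first molecule of each species is stored in the provenance.
#' @param initPositions optional list (one entry per species) of n x 2
#'   matrices of initial molecule positions (x, y) in micrometres,
#'   overriding the uniform random placement; the molecule count of a
#'   species with given positions is the row count of its matrix.
#' @return A \linkS4class{SpectralLineScanStack}; provenance records the
#'   seed, substream seeds and ground-truth species table.
#' @export
simulateLineScan <- function(species, geometry = ScanGeometry(),
                             psf = PSFModel(), boxSize = c(10, 3),
                             seed = 1L, keepTotals = FALSE,
                             trackFirst = FALSE, initPositions = NULL) {
  if (is(species, "SpeciesSpec")) species <- list(species)
  if (length(species) == 0L) stop("at least one species is required")
  if (!all(vapply(species, is, TRUE, "SpeciesSpec")))
    stop("species must be SpeciesSpec objects")
  if (length(boxSize) != 2L || any(boxSize <= 0))
    stop("boxSize must be two positive lengths (x, y) in micrometres")
  if (boxSize[1] < geometry@lineLength)
    stop("the periodic box must be larger than the scan line")
  validObject(geometry)

  bounds <- species[[1]]@spectrum@channelBounds
  for (s in species)
    if (!isTRUE(all.equal(s@spectrum@channelBounds, bounds)))
      stop("all species must share one spectral channel layout")

  nL <- geometry@nLines; nP <- geometry@nPixels
  nC <- nrow(bounds)
  counts <- integer(as.double(nL) * nP * nC)
  totals <- if (keepTotals) integer(as.double(nL) * nP) else integer(0)

  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, length(species))
  tracks <- vector("list", length(species))
  boxArea <- boxSize[1] * boxSize[2]
  for (i in seq_along(species)) {
    s <- species[[i]]
    pos <- if (!is.null(initPositions)) initPositions[[i]] else NULL
    nMol <- if (!is.null(pos)) nrow(pos)
            else max(0L, as.integer(round(s@density * boxArea)))
    if (is.null(pos)) pos <- matrix(0, 0, 2)
    set.seed(subseeds[i])
    res <- .cpp_simulate_species(
      counts, totals, keepTotals, nL, nP, nC,
      geometry@pixelSize, geometry@lineLength, geometry@linePeriod,
      psf@waist, s@D, s@brightness, nMol, boxSize[1], boxSize[2],
      s@spectrum@probabilities, s@mobile, trackFirst, pos)
    tracks[[i]] <- res$track
  }
  dim(counts) <- c(nL, nP, nC)
  nClipped <- sum(counts > 255L)
  if (nClipped > 0L) counts[counts > 255L] <- 255L

  if (geometry@bidirectional) {
    odd <- seq(2L, nL, by = 2L)
    counts[odd, , ] <- counts[odd, nP:1L, , drop = FALSE]
  }

  prov <- list(
    generator = "simulateLineScan", seed = seed, substreamSeeds = subseeds,
    species = data.frame(
      label = vapply(species, function(s) s@label, ""),
      D = vapply(species, function(s) s@D, 0),
      brightness = vapply(species, function(s) s@brightness, 0),
      density = vapply(species, function(s) s@density, 0),
      mobile = vapply(species, function(s) s@mobile, TRUE)),
    waist = psf@waist, boxSize = boxSize, nClipped = nClipped)
  if (keepTotals) {
    dim(totals) <- c(nL, nP)
    prov$totals <- totals
  }
  if (trackFirst) prov$tracks <- tracks

  SpectralLineScanStack(counts, geometry, bounds, provenance = prov,
                        reordered = FALSE)
}

#' Reference spectra for the detector channel presets
#'
#' Returns the spectral channel bounds of the two detector
#' configurations used for FSCS acquisition: six channels (495-510,
#' 511-530, 531-560, 561-610, 611-630, 631-680 nm) or ten channels
#' (481-499 through 655-673 nm in 18-19 nm steps).
#'
#' @param preset "six" or "ten".
#' @return two-column matrix of channel bounds (nm).
#' @export
channelPreset <- function(preset = c("six", "ten")) {
  preset <- match.arg(preset)
  if (preset == "six")
    cbind(c(495, 511, 531, 561, 611, 631),
          c(510, 530, 560, 610, 630, 680))
  else
    cbind(c(481, 500, 519, 539, 558, 577, 596, 617, 636, 655),
          c(499, 518, 538, 557, 576, 595, 616, 635, 654, 673))
}

#' Synthetic dichroic-filtered emission spectra
#'
#' Emission spectra of a green (GFP-like, peak ~508 nm) and a red
#' (mCherry-like, peak ~610 nm) fluorophore, modelled as skewed
#' Gaussians integrated over the channel gates of the chosen detector
#' preset.  These are synthetic stand-ins for measured reference dye
#' spectra, intended for simulation and testing.
#'
#' @param kind "green" or "red".
#' @param preset detector preset, see \code{\link{channelPreset}}.
#' @return An \linkS4class{EmissionSpectrum}.
#' @export
syntheticSpectrum <- function(kind = c("green", "red"),
                              preset = c("six", "ten")) {
  kind <- match.arg(kind)
  bounds <- channelPreset(preset)
  peak <- if (kind == "green") 508 else 610
  width <- if (kind == "green") 22 else 30
  # skewed profile: Gaussian rise, exponential red tail
  dens <- function(l) ifelse(l < peak, exp(-(l - peak)^2 / (2 * width^2)),
                             exp(-(l - peak) / (1.8 * width)))
  p <- vapply(seq_len(nrow(bounds)), function(i) {
    stats::integrate(dens, bounds[i, 1], bounds[i, 2])$value
  }, 0)
  EmissionSpectrum(bounds, p / sum(p))
}
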