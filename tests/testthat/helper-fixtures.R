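# Shared fixtures, built in code.

# single "white" channel: spectral splitting is a no-op
oneChannelSpectrum <- function() EmissionSpectrum(cbind(495, 680), 1)

smallGeometry <- function(nLines = 2000L, bidirectional = TRUE)
  ScanGeometry(nLines = nLines, bidirectional = bidirectional)

# default mobile species at the study brightness/density
mobileSpecies <- function(D = 1, spectrum = oneChannelSpectrum(),
                          brightness = 1, density = 20, label = "mobile")
  SpeciesSpec(label, D, brightness, density, spectrum)

# disk footprint for radial-mask geometry oracles
diskFootprint <- function(size = 160L, radius = 60) {
  m <- matrix(FALSE, size, size)
  c0 <- (size + 1) / 2
  rr <- sqrt((row(m) - c0)^2 + (col(m) - c0)^2)
  rr <= radius
}

# noiseless translocation movie, membrane fraction ramped 0.5 -> 0.9
rampMovieSpec <- function(photonScale = 0, gaussianSd = 0, nFrames = 20L)
  CellMovieSpec(imageShape = c(80L, 80L), nFrames = nFrames,
                center = c(40, 40), radii = c(25, 30),
                shellFraction = 0.25,
                channels = list(cellChannel(
                  "sensor", totalIntensity = 3e4,
                  membraneFraction = seq(0.5, 0.9, length.out = nFrames))),
                photonScale = photonScale, gaussianSd = gaussianSd)

# closed-form single-species surface on a fine log grid
closedFormSurface <- function(D = 1, w = 0.25, A = 1, offset = 0,
                              tau = 10^seq(-6, 0.3, by = 0.05),
                              delta = seq(0, 0.5, by = 0.021)) {
  G <- diffusionModel(tau, delta, offset, A, D, w)
  new("CorrelationSurface", lagTimes = tau, spatialLags = delta, G = G,
      nSamples = rep(1, length(tau)), waist = w, waistSe = numeric(0),
      segment = "line-average")
}

surfaceCurve <- function(surface)
  new("CorrelationCurve", lagTimes = surface@lagTimes,
      G = surface@G[, 1], nSamples = surface@nSamples,
      species = c("a", "a"))
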