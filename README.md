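# lineFSCS

Line-scanning fluorescence **spectral** correlation spectroscopy (FSCS)
and confocal image quantification, for mapping membrane-protein
diffusion along a scanned line while separating spectrally overlapping
fluorophores — e.g. a GFP-tagged kinase co-expressed with an
mCherry-tagged, optogenetically clusterable substrate — plus the image
statistics used alongside such experiments (membrane translocation,
Otsu-gated colocalization, Ca²⁺ flux, cluster metrics).

## What it computes

The raw datum is an 8-bit photon-count stack `[line, pixel, spectral
channel]` from a bidirectionally scanned confocal line (default: 5.355
µm / 256 px / 0.51 µs dwell / 154 µs line period). The analysis chain:

1. **Spectral filters** — from normalized reference spectra *M* and the
   sample's mean spectrum *s*, the weighted least-squares unmixer
   `F = (MᵀWM)⁻¹MᵀW`, `W = diag(1/sⱼ)`, assigning every detected photon
   a per-species weight (counts scale the weight on multiphoton dwells).
2. **Filtered correlation** — multi-tau estimator (8 points/octave,
   base lag = line period, symmetric normalization) of the fluctuation
   correlation `G(τ) = ⟨Fₐ(t)F_b(t+τ)⟩ / (⟨Fₐ⟩⟨F_b⟩) − 1` per pixel
   column, averaged at the correlation level.
3. **Beam waist** — Gaussian fit of the spatial cross-correlation of
   pixel pairs at the minimal temporal lag: `G(δ) ∝ exp(−δ²/w²)`;
   no reference-dye calibration.
4. **Diffusion** — weighted fit of the 2D n-species free-diffusion
   model
   `G(t,δ) = G_offset + Σᵢ Aᵢ (4Dᵢt + w²)⁻¹ exp(−δ²/(4Dᵢt + w²))`,
   and a fitting-free estimator: spline-smoothed extrapolation of G(0),
   half-amplitude transition time γ_D, `D = w²/(4γ_D)`.
5. **Segment profiles** — the line split into 20 ≈250-nm segments, each
   a single-point FCS measurement: per-segment D vs partner-channel
   intensity, with their Pearson correlation.
6. **Image stages** — ROI SD traces, kymographs, the Ca²⁺ fold
   statistic, dual-Otsu co-transfection gating and expression-normalized
   staining, Sobel-based cell detection, radial membrane/cytosol masks,
   translocation traces, and Otsu-filtered Pearson colocalization.

Synthetic generators (`simulateLineScan`, `simulateCellMovie`) produce
both data types with known ground truth; every stage is validated
against them or against closed-form/brute-force oracles.

## Worked example

```r
library(lineFSCS)

## one mobile species, D = 1 um^2/s, on the default scan geometry
stack <- simulateLineScan(
  SpeciesSpec("kinase", D = 1, brightness = 1, density = 20,
              spectrum = EmissionSpectrum(cbind(495, 680), 1)),
  ScanGeometry(), PSFModel(waist = 0.25), seed = 7)
stack <- reorderBidirectional(stack)

surf <- assembleSurface(stack, 1, deltaPx = seq(0, 24, 4),
                        colStride = 4L, maxDelta = 0.5)
fit  <- fitNSpecies(surf, 1)
fit
#> DiffusionFitResult: 1 species, waist 0.256 um
#>   D1 = 0.9563 um^2/s, A1 = 0.01793
#>   offset = -0.01099, residual RMS = 0.003913

curve <- new("CorrelationCurve", lagTimes = lagTimes(surf),
             G = corrValues(surf)[, 1], nSamples = surf@nSamples,
             species = c("kinase", "kinase"))
transitionTime(curve, beamWaist(surf))
#> TransitionTimeResult: G0 = 0.2628, gammaD = 0.01585 s, D = 1.033 um^2/s (w = 0.256 um)
```

The fitted and fitting-free estimates bracket the ground truth
(D = 1 µm²/s, w = 0.25 µm): the surface fit recovers D within ~4% and
the beam waist within ~2% on this seed, and the transition-time
estimate agrees with the fit — on real data, where a single component
does not describe the kinase, the two estimators are used together
exactly this way (the fit as a model check, the transition time as the
model-free readout).

A YAML-driven pipeline (`runPipeline()`, stages `simulate_linescan`,
`filters`, `fscs`, `profile`, `simulate_cells`, `translocation`,
`pearson`, `calcium`, `clusterstd`, `kymograph`) writes TSV/TIFF
artifacts with the seed and a config hash in every header; a thin CLI
wrapper lives at `inst/cli/linefscs.R`.

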