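---
title: "Line-scanning FSCS and confocal image quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-scanning FSCS and confocal image quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineFSCS)
```

# The measurement

A confocal beam is swept bidirectionally along a single line of the
basolateral plasma membrane (default geometry: 5.355 µm over 256 pixels
of 21 nm, 0.51 µs per pixel dwell, 154 µs per line), while a
photon-counting detector records counts in 6 or 10 spectral channels.
Each pixel column of the resulting (line × pixel × channel) stack is a
time series sampled once per line period; correlating these series
reports on the diffusion of fluorescently tagged membrane proteins —
here, a membrane-anchored kinase imaged together with an optogenetically
clusterable substrate — while the spectral dimension lets two
spectrally overlapping fluorophores be separated *statistically* rather
than by hard emission gates.

`lineFSCS` implements the full analysis chain on this data model, plus
the companion confocal image quantification procedures (translocation,
colocalization, Ca²⁺ flux, cluster metrics), and — because the raw
measurements are photon streams with no public ground truth — a
simulator for both data types so every stage is testable end to end.

# Spectral filters (filtered FCS)

Let $M$ be the matrix whose columns are the intensity-normalized
reference emission spectra of the species (after all dichroics), and let
$s_j$ be the mixed sample spectrum — here always the per-channel mean
count of the stack being analysed, so filters are recalculated per
sample and then treated as constants. The statistical filters are the
weighted least-squares unmixer

$$ F = (M^\top W M)^{-1} M^\top W, \qquad W = \mathrm{diag}(1/s_j), $$

the classical filtered-FCS construction: $F M = I$ exactly (each filter
reproduces its own reference and rejects the others), and whenever the
mixed spectrum is an exact nonnegative combination of the references the
filters sum to one in every channel. The Poisson assumption motivates
$W$: the variance of a photon-count channel equals its mean, so
channels are weighted inversely to their counting noise. Whether the
original analysis weighted by the mean or by an empirical variance is
not documented; the mean is used here and the per-channel sum-to-one
property is asserted as a diagnostic (tolerance 1e-3 on simulated data)
rather than imposed by renormalization.

A dwell that registers $n$ photons in channel $j$ contributes $n f_j$
to the filtered intensity — multiphoton dwells are up-weighted by their
count, which matters because the 0.51 µs dwell is long against the
~100 ns detector dead time and multi-photon registrations are common at
membrane-protein expression levels.

# Correlation analysis

For a species filter $f$ the filtered intensity of pixel column $p$ is
$F_p(t)=\sum_j f_j I_{j,p}(t)$, sampled at the line period. The stored
correlation is the *fluctuation* part

$$ G(\tau) = \frac{\langle F_a(t)\,F_b(t+\tau)\rangle}
  {\langle F_a\rangle \langle F_b\rangle} - 1 , $$

i.e. the raw normalized correlator minus one, so that the diffusion
model's offset plays its usual role and curves decay to ~0. Estimation
uses a multi-tau scheme (register size 16, eight points per octave,
base lag = one line period, capped at a quarter of the record) with
symmetric normalization: the means in the denominator are taken over
the overlapping window at each lag, which suppresses slow-drift bias.
Per-column correlations are averaged at the correlation level — never
by pooling intensities — which preserves the equivalence of a line
segment to a raw single-point FCS measurement. A plain $O(N^2)$
direct-sum estimator (`directCorrelation`) is exported as an
independent cross-check; the multi-tau estimator agrees with it to
machine precision at unbinned lags and to well under 2% at binned lags
on smooth curves.

Two estimator caveats are documented because the tests exercise them:
the normalized single-record estimator carries a negative bias of order
$\sigma^2/(\mu^2 M)$ at window length $M$ even for white noise, and for
2D diffusion (whose correlation integral grows logarithmically) the
tail of slow components is suppressed when the record is only tens of
transit times long. Both effects scale with the amplitude $G(0) \sim
1/N_{\mathrm{eff}}$, which is why the simulator's default density is
chosen in the realistic many-molecule regime (below).

## Spatial cross-correlation and the beam waist

Correlating column pairs separated by $\delta$ at the minimal temporal
lag (one line period — the closest observable stand-in for $t = 0$ with
a single scanned beam) gives a Gaussian profile $G(\delta) \propto
\exp(-\delta^2/w^2)$, because the model at $t \to 0$ reduces to the
detection-profile overlap. Fitting amplitude, width and a small
constant offset recovers the beam waist $w$ (equivalently
$w = \mathrm{FWHM}/(2\sqrt{\ln 2})$) from the data themselves — no
reference-dye calibration. The offset term absorbs the finite-record
normalization bias, which otherwise narrows the recovered waist by a
few percent; on noiseless closed-form profiles it fits to zero and the
inversion is exact.

## The spatio-temporal surface and the diffusion model

The assembled surface $G(t,\delta)$ is fitted by the 2D $n$-species
free-diffusion model

$$ G(t, \delta) = G_{\mathrm{offset}} + \sum_i A_i\,
   \frac{1}{4 D_i t + w^2}\,
   \exp\!\Big(\!-\frac{\delta^2}{4 D_i t + w^2}\Big), $$

with $w$ held fixed at the spatial-correlation estimate. Fitting is
weighted (by the square root of samples per lag) Levenberg–Marquardt
with multi-start initialization over $D \in \{0.01, 0.1, 1, 10\}$
µm²/s per species (all ascending combinations), amplitudes seeded from
$G$ at the smallest lags times $w^2$, the offset from the tail mean;
amplitudes are bounded below by zero and $D$ is fitted on a log scale.
Species are reported in ascending $D$, which makes the (label-
permutation-symmetric) fit deterministic. At most three species are
supported; beyond two, identifiability on realistic records is poor and
untested.

## Fitting-free transition time

For heterogeneous or multi-component diffusion where a parametric fit
is not warranted, the transition time $\gamma_D$ is estimated with no
model assumption: smooth the curve with a cubic smoothing spline in
log-lag space (smoothing chosen by generalized cross-validation by
default, overridable), extrapolate to a pseudo-lag of one tenth of the
minimal lag to estimate $G(0)$ (a log-lag grid has no $\tau = 0$
point), and interpolate the lag at which the smoothed curve crosses
$G(0)/2$ between the bracketing grid points. Then
$D = w^2/(4\gamma_D)$. On the closed-form single-species curve the
half-crossing sits at exactly $w^2/4D$; the pseudo-lag extrapolation
reproduces it to ~0.02% when the grid reaches down to microsecond lags
and to ~0.2–3% when the grid starts at one line period (the linear
log-lag extrapolation slightly overshoots a curve that is still
flattening). This estimator is deliberately variance-prone on noisy
segments — it leans entirely on the local shape of the curve — which
is why segment-level analyses report medians and an exclusion count
rather than imputing failed segments.

## Line segmentation

The 256-pixel line is split into 20 contiguous 12-pixel segments
(~250 nm each, the remainder trimmed equally from both ends), each the
equivalent of a raw single-point FCS measurement. Per segment, the
kinase-channel autocorrelation yields a transition-time $D$ and the
partner (cluster) channel yields a mean filtered intensity; their
Pearson correlation across segments asks whether the kinase slows down
where the clusters sit. Segments whose curves do not decay are
excluded and counted, not imputed.

# The synthetic photon-stream generator

Mobile molecules perform 2D Brownian steps (variance $2 D \Delta t$ per
axis per line period) in a periodic box (default 10 µm × 3 µm, centred
on the line) so density stays stationary; immobile species — standing
in for the stable, largely immobile optogenetic clusters — keep fixed
positions. The detected rate at a pixel dwell is
$\sum_{\mathrm{molecules}} B\,\exp(-2 r^2/w^2)$ with $B$ the per-dwell
molecular brightness and $r$ the molecule-to-beam distance; counts are
Poisson draws split multinomially across spectral channels by the
species' emission spectrum, summed over species, clipped at 255 (the
8-bit registration of the real acquisition), and odd lines are written
in reversed pixel order when the geometry is bidirectional.

Choices a user should know:

* **Motion is updated once per line period**, not per dwell: the dwell
  is ~300× shorter than the line period, so intra-line motion is
  negligible at membrane-protein $D$ — and the simulation is ~300×
  faster.
* **Brightness and density defaults** (1.0 counts/dwell at beam centre;
  20 molecules/µm²) are free parameters of the fixture — the original
  study reports neither for its kinase — chosen at the scale of an
  overexpressed membrane protein. The density choice also keeps
  $G(0) \approx 0.3$, where the single-record estimator biases
  discussed above are ~1% of the amplitude rather than comparable to
  it, as they become in the few-molecule regime.
* **Detector dead time is modelled only as the 0–255 clip**; explicit
  pile-up is not simulated because the analysis handles multiphoton
  registration by count weighting, not by simulation.
* **Seeding**: one integer seed expands into independent per-species
  substreams (recorded in the stack provenance), so adding a species
  never perturbs the photon stream of the others.
* **Not modelled**: 3D diffusion, photobleaching, blinking, triplet
  kinetics, and the light-driven clustering kinetics themselves.
  Passing tests therefore validate the estimators on ideal free
  diffusion plus shot noise; they do not certify behaviour under
  bleaching or anomalous diffusion.

The cell-movie generator plays the same role for the image stages: an
elliptical cell whose per-channel intensity is split between a
peripheral membrane shell and the cytosol core by a per-frame membrane
fraction, with optional punctate clusters appearing at an onset frame,
under Poisson photon noise and Gaussian read noise, with the full
ground truth (per-frame membrane fraction, cluster coordinates,
intensity time courses) returned alongside the movie.

# Image quantification

All procedures operate on `[frame, y, x, channel]` arrays with 1-based
R indexing.

* **ROI SD trace** uses the population (divide-by-*n*) standard
  deviation; cluster formation raises within-ROI variance, so the trace
  steps up at the clustering onset.
* **Ca²⁺ fold increase** is (mean of last six frames − mean of first
  six)/(mean of first six).
* **Co-transfection gating** takes the logical AND of per-channel Otsu
  foregrounds; Otsu thresholds are computed on 256-bin histograms over
  each channel's intensity range. Staining is then quantified as
  (mean stain − background)/(mean expression) inside the mask, with the
  background measured by the caller on cells lacking the kinase.
  Whether the original background standardization subtracted or divided
  is not recoverable from the published values; subtraction is
  implemented.
* **Cell detection** is Sobel gradient → Otsu threshold → dilation →
  hole filling → erosion (including one extra erosion step compensating
  the outward half of the gradient band) → opening → largest connected
  component. On a noiseless disk the footprint overlaps the truth with
  IoU ≥ 0.95.
* **Radial masks**: each footprint pixel gets a normalized radial
  coordinate $\hat r = d_C/(d_C + d_E)$ (distance to the centre of mass
  over its sum with the distance-transform distance to the edge), 0 at
  the centre, 1 at the edge. The membrane is the *outer* shell
  ($\hat r \ge 1 - b$, default $b = 0.25$): the source text's literal
  "0 to 0.25" interval contradicts the membrane's peripheral location
  and is taken to be an inverted statement of the same convention; the
  literal inner-interval reading remains available as
  `convention = "inner"`. On a disk the default shell covers
  $1 - 0.75^2 = 43.75\%$ of the footprint.
* **Translocation** is the membrane/cytosol mean-intensity ratio per
  frame, normalized to the mean ratio of the first four frames.
* **Pearson colocalization** removes background by per-channel Otsu
  thresholding and retains the union of the two foregrounds (the
  combination rule is not specified in the source; intersection is
  available as an option), then computes the standard Pearson
  coefficient. The published formula's denominator repeats the
  green-channel sum of squares — an evident typo; the standard
  $\sqrt{\sum(G_i-\bar G)^2 \sum(R_i-\bar R)^2}$ is used.

# Numerical and design notes

* Degenerate inputs error early and specifically: constant images for
  Otsu, non-decaying curves for the transition time, collinear
  reference spectra, empty masks, ragged TIFFs, re-reordering an
  already reordered stack.
* The line-scan container is a self-describing binary file (magic
  string, JSON header carrying schema version, geometry, channel
  bounds and provenance, then the uint8 count array); it replaces the
  original acquisition software's proprietary container with something
  any language can read in a few lines.
* Hyperstack TIFFs quantize samples to 32 bits over [0, 1] with the
  scale recorded in a JSON sidecar; integer-valued movies (photon
  counts) round-trip exactly, other data to ~2⁻³² relative.
* Pipeline runs embed a config hash and the seed in every TSV header;
  identical config + seed reproduces byte-identical outputs (creation
  timestamps live only in the binary container's provenance, never in
  TSVs).

# Problem sizes used in the validation suite

The acceptance-level checks simulate the full acquisition geometry at
50,000 lines (7.7 s of scanning) — enough for the estimators to reach
their asymptotic behaviour at membrane-protein diffusion coefficients
(0.1–2 µm²/s) while a 4 × 10-seed recovery study completes in minutes
on one core. Full-scale acquisitions (300,000 lines) simply extend the
record; nothing in the code depends on the desk-scale default.

# Known limitations

* Two-species fits on realistic single-record data are
  identifiability-limited; the two-component results in the validation
  suite use noiseless closed-form surfaces to separate model capacity
  from estimator noise.
* The transition-time estimator's $G(0)$ extrapolation is the dominant
  variance source on noisy segments; its median over segments or seeds
  is stable, single values are not.
* The waist recovery assumes the minimal-lag spatial profile is
  diffusion-free; at $4 D T_{\mathrm{line}} \ll w^2$ (true for all
  membrane-protein cases here) the induced bias is < 1%.
* No bleaching, blinking or anomalous-diffusion corrections anywhere.
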