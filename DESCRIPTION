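Package: lineFSCS
Title: Line-Scanning Fluorescence Spectral Correlation Spectroscopy and
    Confocal Image Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for line-scanning fluorescence spectral correlation
    spectroscopy (FSCS) on photon-counting line-scan data: statistical
    spectral filters that unmix photon counts into species-specific
    contributions, multi-tau filtered auto- and cross-correlation,
    spatial cross-correlation recovery of the beam waist, fitting of the
    two-dimensional n-species free-diffusion model, and a fitting-free
    transition-time estimator of membrane diffusion coefficients.  Also
    implements the companion confocal image quantification procedures
    (ROI standard-deviation cluster traces, kymographs, Ca2+ fold
    statistics, Otsu-gated co-transfection normalization, radial
    membrane/cytosol translocation analysis, and Otsu-filtered Pearson
    colocalization) together with synthetic photon-stream and cell-movie
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
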