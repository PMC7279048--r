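test_that("bidirectional reorder restores a common orientation and is guarded", {
  g <- ScanGeometry(nLines = 4L, bidirectional = TRUE)
  counts <- array(0L, c(4, 256, 1))
  base <- as.integer(round(50 * exp(-((1:256) - 77)^2 / 200)))
  for (l in 1:4) counts[l, , 1] <- if (l %% 2 == 0) rev(base) else base
  st <- SpectralLineScanStack(counts, g, cbind(495, 680))
  r <- reorderBidirectional(st)
  for (l in 2:4) expect_identical(r@counts[l, , 1], r@counts[1, , 1])
  expect_error(reorderBidirectional(r), "already")
  # unidirectional stacks pass through unchanged
  gU <- ScanGeometry(nLines = 4L, bidirectional = FALSE)
  stU <- SpectralLineScanStack(counts, gU, cbind(495, 680))
  expect_identical(reorderBidirectional(stU), stU)
})

test_that("constant series have zero fluctuation correlation at every lag", {
  g <- ScanGeometry(nLines = 1000L, bidirectional = FALSE)
  counts <- array(3L, c(1000, 256, 1))
  st <- SpectralLineScanStack(counts, g, cbind(495, 680))
  cur <- temporalCorrelation(st, 1)
  expect_lt(max(abs(corrValues(cur))), 1e-12)
})

test_that("alternating series matches the direct-sum correlator at lag one", {
  g <- ScanGeometry(nLines = 1000L, bidirectional = FALSE)
  counts <- array(rep(c(1L, 2L), 500), c(1000, 256, 1))
  st <- SpectralLineScanStack(counts, g, cbind(495, 680))
  cur <- temporalCorrelation(st, 1)
  x <- rep(c(1, 2), 500)
  expect_equal(corrValues(cur)[1], directCorrelation(x, lags = 1L),
               tolerance = 1e-12)
})

test_that("independent Poisson counts are uncorrelated at all lags", {
  # sampling-error oracle from repeated seeds
  reps <- 8L
  g <- ScanGeometry(lineLength = 64 * 0.021, nPixels = 64L,
                    nLines = 2000L, bidirectional = FALSE)
  Gs <- sapply(seq_len(reps), function(r) {
    set.seed(100 + r)
    counts <- array(rpois(2000 * 64, 1.5), c(2000, 64, 1))
    counts[counts > 255] <- 255
    st <- SpectralLineScanStack(counts, g, cbind(495, 680))
    corrValues(temporalCorrelation(st, 1))
  })
  m <- rowMeans(Gs)
  se <- apply(Gs, 1, sd) / sqrt(reps)
  # the normalized estimator carries a documented finite-record bias of
  # order sigma^2 / (mu^2 (N - k)) (= 1/(mu (N - k)) for Poisson data);
  # the null holds to within 3.5 SE once that allowance is granted
  lagGrid <- lineFSCS:::.cpp_multitau_pairs(
    matrix(rnorm(2000, 10), ncol = 1), 0L, 0L, 16L, 500)$lag
  allowance <- 1 / (1.5 * (2000 - lagGrid))
  expect_true(all(abs(m) < 3.5 * se + allowance))
})

test_that("multi-tau equals the direct-sum correlator on 2000-line fixtures", {
  set.seed(42)
  n <- 2000L
  m <- sapply(1:16, function(j)
    as.numeric(stats::arima.sim(list(ar = exp(-1 / 100)), n)) + 10)
  r <- lineFSCS:::.cpp_multitau_pairs(m, 0:15, 0:15, 16L, 256)
  dir <- rowMeans(sapply(1:16, function(j)
    directCorrelation(m[, j], lags = as.integer(round(r$lag)))))
  guard <- abs(dir) > 0.1 * abs(dir[1])   # away from zero crossings
  expect_true(all(abs(r$G - dir)[guard] / abs(dir)[guard] < 0.02))
  # unbinned lags are the identical estimator
  expect_equal(r$G[r$lag <= 16], dir[r$lag <= 16], tolerance = 1e-12)
})

test_that("autocorrelation amplitude scales inversely with molecule density", {
  g <- ScanGeometry(nLines = 20000L)
  amp <- vapply(c(20, 10), function(dens) {
    st <- reorderBidirectional(simulateLineScan(
      mobileSpecies(density = dens), g, seed = 21))
    mean(corrValues(temporalCorrelation(st, 1))[1:3])
  }, 0)
  expect_lt(abs(amp[2] / amp[1] - 2), 0.3)  # doubled within 15%
})

test_that("spatial profile inverts a closed-form Gaussian exactly", {
  delta <- seq(0, 0.5, by = 0.021)
  prof <- lineFSCS:::.fitGaussianProfile(delta, exp(-delta^2 / 0.25^2))
  expect_lt(abs(prof$waist - 0.25), 1e-6)
  expect_error(spatialCrossCorrelation(
    reorderBidirectional(simulateLineScan(mobileSpecies(),
                                          smallGeometry(200L), seed = 1)),
    1, maxDelta = 3), "half the line length")
  expect_error(lineFSCS:::.fitGaussianProfile(c(0, 0.1), c(1, 0.5)),
               "at least 5")
  expect_error(lineFSCS:::.fitGaussianProfile(seq(0, 0.4, 0.1),
                                              rep(0.2, 5)), "decay")
})

test_that("simulated stack recovers the beam waist from the spatial profile", {
  g <- ScanGeometry()  # 50,000 lines
  st <- reorderBidirectional(simulateLineScan(
    mobileSpecies(D = 1), g, psf = PSFModel(0.30), seed = 4))
  sp <- spatialCrossCorrelation(st, 1, maxDelta = 0.6)
  expect_lt(abs(sp$waist - 0.30) / 0.30, 0.10)
})

test_that("surface slices are consistent with their constituent estimators", {
  g <- ScanGeometry(nLines = 4000L)
  st <- reorderBidirectional(simulateLineScan(mobileSpecies(), g, seed = 6))
  surf <- assembleSurface(st, 1, deltaPx = 0:5, colStride = 1L,
                          maxDelta = 0.4)
  cur <- temporalCorrelation(st, 1)
  expect_equal(surf@G[, 1], corrValues(cur), tolerance = 1e-12)
  mat <- filteredIntensity(st, 1)
  spG <- lineFSCS:::.cpp_spatial_profile(mat, 0:5, 1L)
  expect_equal(unname(surf@G[1, ]), unname(spG), tolerance = 1e-10)
})

test_that("line segmentation trims the remainder symmetrically", {
  st <- simulateLineScan(mobileSpecies(), smallGeometry(100L), seed = 1)
  seg <- segmentLine(st, 20L)
  expect_length(seg$segments, 20L)
  expect_true(all(vapply(seg$pixelRanges, length, 0L) == 12L))
  expect_identical(seg$pixelRanges[[1]][1], 9L)          # 8 trimmed left
  expect_identical(seg$pixelRanges[[20]][12], 248L)      # 8 trimmed right
  one <- segmentLine(st, 1L)
  expect_identical(one$pixelRanges[[1]], 1:256)
  expect_error(segmentLine(st, 300L), "exceed")
})

test_that("maxLag beyond a quarter of the record is rejected", {
  st <- reorderBidirectional(simulateLineScan(mobileSpecies(),
                                              smallGeometry(1000L), seed = 1))
  expect_error(temporalCorrelation(st, 1, maxLag = 400), "nLines/4")
})

test_that("cross-correlation of independent species is a null", {
  g <- ScanGeometry(nLines = 20000L)
  species <- list(SpeciesSpec("green", 1, 1, 20, syntheticSpectrum("green")),
                  SpeciesSpec("red", 0.5, 1, 20, syntheticSpectrum("red")))
  st <- reorderBidirectional(simulateLineScan(species, g, seed = 13))
  fs <- stackFilters(st, list(syntheticSpectrum("green"),
                              syntheticSpectrum("red")),
                     labels = c("green", "red"))
  ampl <- function(cur) mean(corrValues(cur)[1:4])
  aG <- ampl(temporalCorrelation(st, fs, speciesA = "green"))
  aR <- ampl(temporalCorrelation(st, fs, speciesA = "red"))
  aX <- ampl(temporalCorrelation(st, filterMatrix(fs)[1, ],
                                 filterMatrix(fs)[2, ]))
  expect_lt(abs(aX), 0.1 * sqrt(aG * aR))
})
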