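test_that("geometry and spectrum invariants are enforced", {
  expect_error(ScanGeometry(pixelSize = 0.03), "lineLength")
  expect_error(ScanGeometry(pixelDwell = 1e-3), "linePeriod")
  expect_error(ScanGeometry(nPixels = -5L), "positive")
  expect_error(EmissionSpectrum(cbind(c(495, 505), c(510, 530)),
                                c(0.5, 0.5)), "non-overlapping")
  expect_error(SpeciesSpec("x", 0, 1, 1, oneChannelSpectrum(),
                           mobile = TRUE), "mobile")
  expect_error(SpeciesSpec("x", 1, 1, 0, oneChannelSpectrum()), "density")
})

test_that("zero brightness yields an all-zero stack", {
  s <- SpeciesSpec("dark", 1, 0, 5, oneChannelSpectrum())
  st <- simulateLineScan(s, smallGeometry(200L), seed = 1)
  expect_true(all(photonCounts(st) == 0L))
})

test_that("identical seeds give identical stacks, different seeds differ", {
  g <- smallGeometry(500L)
  s <- mobileSpecies()
  a <- simulateLineScan(s, g, seed = 11)
  b <- simulateLineScan(s, g, seed = 11)
  c <- simulateLineScan(s, g, seed = 12)
  expect_identical(photonCounts(a), photonCounts(b))
  expect_false(identical(photonCounts(a), photonCounts(c)))
})

test_that("simulator rejects invalid inputs", {
  expect_error(simulateLineScan(list(), smallGeometry(100L)),
               "at least one species")
  expect_error(simulateLineScan(mobileSpecies(), smallGeometry(100L),
                                boxSize = c(-1, 3)), "positive")
  expect_error(simulateLineScan(mobileSpecies(), smallGeometry(100L),
                                boxSize = c(2, 3)), "larger than the scan")
})

test_that("an immobile molecule on the beam path gives its brightness as mean count", {
  # Monte-Carlo mean vs the analytic Poisson mean (brightness at r = 0)
  g <- ScanGeometry(nLines = 10000L, bidirectional = FALSE)
  s <- SpeciesSpec("imm", 0, 2, 1e-3, oneChannelSpectrum(), mobile = FALSE)
  pos <- matrix(c(99.5 * 0.021, 0), 1, 2)  # centre of pixel 100, y = 0
  st <- simulateLineScan(s, g, seed = 5, initPositions = list(pos))
  m <- mean(photonCounts(st)[, 100, 1])
  se <- sqrt(2 / g@nLines)
  expect_lt(abs(m - 2), 3 * se)
})

test_that("channel counts conserve the pre-split Poisson totals", {
  g <- ScanGeometry(nLines = 500L, bidirectional = FALSE)
  s <- SpeciesSpec("g", 1, 3, 20, syntheticSpectrum("green"))
  st <- simulateLineScan(s, g, seed = 3, keepTotals = TRUE)
  expect_true(max(photonCounts(st)) < 255L)  # no clipping at this brightness
  sums <- apply(photonCounts(st), c(1, 2), sum)
  expect_identical(unname(sums), unname(st@provenance$totals))
})

test_that("mobile molecules satisfy the Brownian mean-squared displacement", {
  g <- ScanGeometry(nLines = 10001L, bidirectional = FALSE)
  s <- mobileSpecies(D = 1, brightness = 0, density = 1e-3)
  st <- simulateLineScan(s, g, seed = 5, trackFirst = TRUE,
                         initPositions = list(matrix(c(2.7, 0), 1, 2)))
  tr <- st@provenance$tracks[[1]]
  dx <- diff(tr[, 1]); dy <- diff(tr[, 2])
  dx <- dx - 10 * round(dx / 10)   # unwrap periodic box
  dy <- dy - 3 * round(dy / 3)
  x <- cumsum(dx); y <- cumsum(dy)
  for (m in c(1L, 5L, 20L)) {
    msd <- mean((x[-seq_len(m)] - head(x, -m))^2 +
                (y[-seq_len(m)] - head(y, -m))^2)
    expect_lt(abs(msd / (4 * 1 * m * g@linePeriod) - 1), 0.05)
  }
})

test_that("clipping at 255 is negligible at default brightness", {
  st <- simulateLineScan(mobileSpecies(), smallGeometry(2000L), seed = 1)
  frac <- st@provenance$nClipped / length(photonCounts(st))
  expect_lt(frac, 0.001)
})

test_that("bidirectional stacks store odd lines reversed", {
  g <- ScanGeometry(nLines = 400L, bidirectional = TRUE)
  gU <- ScanGeometry(nLines = 400L, bidirectional = FALSE)
  s <- SpeciesSpec("imm", 0, 3, 1e-3, oneChannelSpectrum(), mobile = FALSE)
  pos <- list(matrix(c(1.05, 0), 1, 2))
  a <- simulateLineScan(s, g, seed = 2, initPositions = pos)
  b <- simulateLineScan(s, gU, seed = 2, initPositions = pos)
  expect_identical(photonCounts(a)[1, , 1], photonCounts(b)[1, , 1])
  expect_identical(photonCounts(a)[2, , 1], rev(photonCounts(b)[2, , 1]))
})

test_that("cell movie: zero noise and constant intensity give identical frames", {
  spec <- CellMovieSpec(nFrames = 6L, channels = list(cellChannel()))
  sim <- simulateCellMovie(spec, seed = 1)
  fr <- movieFrames(sim$movie)
  for (t in 2:6) expect_identical(fr[t, , , 1], fr[1, , , 1])
})

test_that("cell movie: ramped membrane fraction raises shell intensity monotonically", {
  sim <- simulateCellMovie(rampMovieSpec(), seed = 1)
  fr <- movieFrames(sim$movie)
  shell <- sim$truth$membrane
  means <- vapply(seq_len(dim(fr)[1]),
                  function(t) mean(fr[t, , , 1][shell]), 0)
  expect_true(all(diff(means) > 0))
})

test_that("cell movie: clusters raise the in-cell intensity SD after onset", {
  ch <- cellChannel("a", totalIntensity = 1e4, membraneFraction = 0.5,
                    nClusters = 5L, clusterRadius = 2,
                    clusterAmplitude = 5 * 1e4 / 3000, onsetFrame = 10L)
  spec <- CellMovieSpec(imageShape = c(80L, 80L), nFrames = 20L,
                        center = c(40, 40), radii = c(25, 30),
                        channels = list(ch))
  sim <- simulateCellMovie(spec, seed = 2)
  fr <- movieFrames(sim$movie)
  fp <- sim$truth$footprint
  sdIn <- function(t) {
    v <- fr[t, , , 1][fp]
    sqrt(mean((v - mean(v))^2))
  }
  expect_gt(sdIn(11), sdIn(9))
})

test_that("cell movie ground truth matches recomputation from noiseless frames", {
  sim <- simulateCellMovie(rampMovieSpec(), seed = 3)
  fr <- movieFrames(sim$movie)
  shell <- sim$truth$membrane
  for (t in c(1L, 10L, 20L)) {
    mf <- sum(fr[t, , , 1][shell]) / sum(fr[t, , , 1])
    expect_lt(abs(mf - sim$truth$membraneFraction[t, 1]), 1e-6)
  }
})

test_that("cell movie spec rejects invalid geometry", {
  expect_error(CellMovieSpec(shellFraction = 1.2), "shellFraction")
  expect_error(CellMovieSpec(center = c(5, 5), radii = c(20, 20)),
               "inside the frame")
  expect_error(CellMovieSpec(channels = list(cellChannel(
    onsetFrame = 50L, nClusters = 1L))), "onset")
})
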