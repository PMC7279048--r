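test_that("ROI standard deviation is the population SD per frame", {
  frames <- array(5, c(3, 8, 8, 1))
  frames[2, 1:2, 1:2, 1] <- c(0, 0, 2, 2)
  st <- TimeLapseStack(frames)
  tr <- roiStdTrace(st, c(1, 2, 1, 2))
  expect_equal(tr, c(0, 1, 0))
  expect_error(roiStdTrace(st, c(0, 2, 1, 2)), "rectangle")
})

test_that("ROI SD trace rises after cluster onset in a synthetic clustering movie", {
  ch <- cellChannel("a", totalIntensity = 1e4, membraneFraction = 0.5,
                    nClusters = 6L, clusterRadius = 2,
                    clusterAmplitude = 15, onsetFrame = 8L)
  spec <- CellMovieSpec(imageShape = c(80L, 80L), nFrames = 15L,
                        center = c(40, 40), radii = c(25, 30),
                        channels = list(ch))
  sim <- simulateCellMovie(spec, seed = 4)
  tr <- roiStdTrace(sim$movie, c(15, 65, 10, 70))
  expect_gt(min(tr[9:15]), max(tr[1:7]))
})

test_that("kymograph reports static, stationary and moving structures", {
  frames <- array(0, c(5, 20, 20, 1))
  frames[, 10, 5, 1] <- 9                       # stationary bright pixel
  st <- TimeLapseStack(frames)
  km <- kymograph(st, c(10, 3, 10, 12))
  expect_true(all(km[3, ] == 9))                # constant row
  expect_true(all(apply(km, 2, function(cl) identical(cl, km[, 1]))))
  # spot advancing one pixel per frame along the line
  mv <- array(0, c(5, 20, 20, 1))
  for (t in 1:5) mv[t, 10, 4 + t, 1] <- 7
  km2 <- kymograph(TimeLapseStack(mv), c(10, 3, 10, 12))
  expect_equal(apply(km2, 2, which.max), 3:7)
  expect_error(kymograph(st, c(10, 5, 10, 5)), "degenerate")
})

test_that("calcium fold increase follows its defining arithmetic", {
  expect_equal(calciumFoldIncrease(c(rep(100, 6), rep(150, 6))), 0.5)
  expect_equal(calciumFoldIncrease(rep(7, 12)), 0)
  expect_error(calciumFoldIncrease(rep(1, 10)), "12 frames")
  expect_error(calciumFoldIncrease(rep(0, 12)), "baseline")
  # exactly linear in the last-six mean at fixed baseline:
  # f(L) = L/base - 1, so doubling L maps f -> 2 f + 1
  base <- rep(10, 6)
  f1 <- calciumFoldIncrease(c(base, rep(20, 6)))
  f2 <- calciumFoldIncrease(c(base, rep(40, 6)))
  expect_equal(f1, 1)
  expect_equal(f2, 2 * f1 + 1)
})

test_that("co-transfection mask is the AND of per-channel Otsu foregrounds", {
  a <- matrix(0, 40, 40); b <- matrix(0, 40, 40)
  a[1:20, ] <- 10; b[21:40, ] <- 10
  expect_true(!any(cotransfectionMask(a, b)))    # disjoint expression
  bi <- matrix(c(rep(0, 800), rep(10, 800)), 40)
  expect_equal(cotransfectionMask(bi, bi), bi > 5)
  expect_error(cotransfectionMask(matrix(1, 4, 4), matrix(1, 4, 4)),
               "constant")
  expect_error(cotransfectionMask(a, b[1:20, ]), "shape")
})

test_that("co-transfection mask isolates co-expressing cells in a synthetic field", {
  set.seed(11)
  a <- matrix(rpois(120 * 120, 2), 120)   # background
  b <- matrix(rpois(120 * 120, 2), 120)
  rr <- function(cy, cx) sqrt((row(a) - cy)^2 + (col(a) - cx)^2)
  co <- rr(35, 35) <= 18                  # co-expressing cell
  single <- rr(85, 85) <= 18              # expresses channel a only
  a[co] <- rpois(sum(co), 60); a[single] <- rpois(sum(single), 60)
  b[co] <- rpois(sum(co), 60)
  mask <- cotransfectionMask(a, b)
  iou <- sum(mask & co) / sum(mask | co)
  expect_gte(iou, 0.95)
})

test_that("normalized staining is background-subtracted per unit expression", {
  mask <- matrix(TRUE, 4, 4)
  stain <- matrix(10, 4, 4); expr <- matrix(5, 4, 4)
  expect_equal(normalizedStaining(stain, expr, mask), 2)
  expect_equal(normalizedStaining(stain, expr, mask, background = 10), 0)
  expect_error(normalizedStaining(stain, expr, mask & FALSE), "empty")
  expect_error(normalizedStaining(stain, matrix(0, 4, 4), mask),
               "positive")
})

test_that("doubling the true phospho fraction doubles the readout under Poisson noise", {
  set.seed(3)
  mask <- diskFootprint(60, 22)
  expr <- matrix(rpois(3600, 200), 60) * mask
  reads <- vapply(c(1, 2), function(frac) {
    stain <- matrix(rpois(3600, 40 * frac + 5), 60)
    normalizedStaining(stain, expr, mask, background = 5)
  }, 0)
  expect_lt(abs(reads[2] / reads[1] - 2), 0.1)
})

test_that("cell detection recovers a disk footprint and fills holes", {
  img <- matrix(0, 100, 100)
  rr <- sqrt((row(img) - 50)^2 + (col(img) - 50)^2)
  img[rr <= 30] <- 10
  fp <- detectCell(img)
  truth <- rr <= 30
  expect_gte(sum(fp & truth) / sum(fp | truth), 0.95)
  holey <- img; holey[rr <= 10] <- 0
  fp2 <- detectCell(holey)
  expect_true(all(fp2[rr <= 8]))
  expect_error(detectCell(matrix(0, 50, 50)), "constant|edges")
})

test_that("radial masks partition a disk with the expected shell area", {
  fp <- diskFootprint(160, 60)
  m <- radialMasks(fp, 0.25)
  expect_true(all((m@membrane | m@cytosol) == fp))
  expect_false(any(m@membrane & m@cytosol))
  frac <- sum(m@membrane) / sum(fp)
  expect_lt(abs(frac - 0.4375), 0.02 * 0.4375 + 0.01)
  expect_equal(sum(radialMasks(fp, 0)@membrane), 0)
  # monotone in the boundary parameter
  areas <- vapply(c(0.1, 0.25, 0.5, 0.9),
                  function(b) sum(radialMasks(fp, b)@membrane), 0)
  expect_true(all(diff(areas) >= 0))
  # inner convention flips the assignment
  inner <- radialMasks(fp, 0.25, convention = "inner")
  expect_lt(sum(inner@membrane) / sum(fp), 0.1)
  expect_error(radialMasks(matrix(FALSE, 5, 5)), "degenerate")
})

test_that("translocation trace is flat for uniform and membrane-constant channels", {
  fp <- diskFootprint(80, 30)
  masks <- radialMasks(fp, 0.25)
  frames <- array(2, c(6, 80, 80, 1))
  tr <- translocationTrace(TimeLapseStack(frames), masks)
  expect_equal(tr@ratio, rep(1, 6), tolerance = 1e-12)
  expect_equal(tr@foldChange, rep(1, 6), tolerance = 1e-12)
  # membrane-anchored control: constant distribution, noisy readout
  ch <- cellChannel("anchor", totalIntensity = 3e4, membraneFraction = 0.7)
  spec <- CellMovieSpec(imageShape = c(80L, 80L), nFrames = 12L,
                        center = c(40, 40), radii = c(25, 30),
                        channels = list(ch), photonScale = 20)
  sim <- simulateCellMovie(spec, seed = 8)
  m2 <- radialMasks(sim$truth$footprint, 0.25)
  tr2 <- translocationTrace(sim$movie, m2)
  expect_lt(max(abs(tr2@foldChange - 1)), 0.05)
})

test_that("translocation fold-change tracks the generator ground truth", {
  noiseless <- simulateCellMovie(rampMovieSpec(), seed = 1)
  masks <- radialMasks(noiseless$truth$footprint, 0.25)
  ref <- translocationTrace(noiseless$movie, masks)
  expect_true(all(diff(ref@foldChange) > 0))
  finalRef <- ref@foldChange[length(ref@foldChange)]
  folds <- vapply(1:10, function(sd) {
    sim <- simulateCellMovie(rampMovieSpec(photonScale = 20,
                                           gaussianSd = 0.02), seed = sd)
    tr <- translocationTrace(sim$movie, masks)
    tr@foldChange[length(tr@foldChange)]
  }, 0)
  expect_true(all(abs(folds / finalRef - 1) < 0.1))
})

test_that("Pearson colocalization matches the direct formula and its invariances", {
  set.seed(5)
  a <- matrix(c(rpois(50, 2), rpois(50, 40)), 10)
  expect_equal(pearsonColocalization(a, a), 1)
  expect_equal(pearsonColocalization(a, 2 * a), 1)       # scale invariance
  expect_equal(pearsonColocalization(a, 2 * a + 3), 1)   # affine invariance
  b <- matrix(c(rpois(50, 2), rpois(50, 40)), 10)
  expect_equal(pearsonColocalization(a, b), pearsonColocalization(b, a))
  # brute-force covariance / (sd sd) on the retained pixels
  keep <- (a > otsuThreshold(a)) | (b > otsuThreshold(b))
  brute <- mean((a[keep] - mean(a[keep])) * (b[keep] - mean(b[keep]))) /
    (sqrt(mean((a[keep] - mean(a[keep]))^2)) *
     sqrt(mean((b[keep] - mean(b[keep]))^2)))
  expect_equal(pearsonColocalization(a, b), brute, tolerance = 1e-12)
  expect_error(pearsonColocalization(a, b[1:5, ]), "shape")
})

test_that("hand-checkable Pearson quartet evaluates to 0.6", {
  # retained pixels a = (1,2,3,4), b = (2,1,4,3); a dark corner below
  # both Otsu thresholds is discarded
  a <- matrix(c(0.01, 0.02, 1, 2, 3, 4), 2)
  b <- matrix(c(0.02, 0.01, 2, 1, 4, 3), 2)
  expect_equal(pearsonColocalization(a, b), 0.6, tolerance = 1e-12)
})
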