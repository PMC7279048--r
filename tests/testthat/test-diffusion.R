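test_that("noiseless single-species surface is recovered to high precision", {
  surf <- closedFormSurface(D = 1, w = 0.25, A = 1)
  fit <- fitNSpecies(surf, 1)
  expect_lt(abs(diffusionCoef(fit) - 1), 1e-4)
  expect_lt(abs(fit@offset), 1e-6)
  expect_lt(fit@residualRms, 1e-8)
})

test_that("flat surface fits to zero amplitude and exact offset", {
  tau <- 10^seq(-4, 0, by = 0.1)
  delta <- seq(0, 0.5, by = 0.05)
  surf <- new("CorrelationSurface", lagTimes = tau, spatialLags = delta,
              G = matrix(0.3, length(tau), length(delta)),
              nSamples = rep(1, length(tau)), waist = 0.25,
              waistSe = numeric(0), segment = "line-average")
  fit <- fitNSpecies(surf, 1)
  expect_lt(abs(fit@amplitudes), 1e-6)
  expect_equal(fit@offset, 0.3, tolerance = 1e-9)
})

test_that("two-species surface needs two components and orders them by D", {
  surf <- closedFormSurface(D = 1, w = 0.25)
  surf@G <- diffusionModel(surf@lagTimes, surf@spatialLags, 0,
                           c(0.5, 0.5), c(0.1, 2), 0.25)
  one <- fitNSpecies(surf, 1)
  two <- fitNSpecies(surf, 2)
  expect_lt(abs(two@D[1] - 0.1) / 0.1, 0.01)
  expect_lt(abs(two@D[2] - 2) / 2, 0.01)
  expect_true(!is.unsorted(two@D))
  expect_gt(one@residualRms, 10 * two@residualRms)
})

test_that("fit preconditions are enforced", {
  surf <- closedFormSurface()
  expect_error(fitNSpecies(surf, 4), "between 1 and 3")
  short <- new("CorrelationSurface", lagTimes = surf@lagTimes[1:5],
               spatialLags = surf@spatialLags,
               G = surf@G[1:5, ], nSamples = rep(1, 5), waist = 0.25,
               waistSe = numeric(0), segment = "line-average")
  expect_error(fitNSpecies(short, 1), "10 temporal")
})

test_that("transition time is exact on the closed-form single-species curve", {
  # half amplitude of A/(4Dt + w^2) sits at t = w^2/4D = 0.015625 s
  surf <- closedFormSurface(D = 1, w = 0.25)
  tt <- transitionTime(surfaceCurve(surf), 0.25)
  expect_lt(abs(tt@gammaD - 0.015625) / 0.015625, 0.005)
  expect_lt(abs(diffusionCoef(tt) - 1), 0.005)
  expect_equal(diffusionCoef(tt), 0.25^2 / (4 * tt@gammaD),
               tolerance = 1e-12)
})

test_that("transition time matches a bisection oracle on a two-species curve", {
  w <- 0.25
  tau <- 10^seq(-6, 0.5, by = 0.05)
  Gfun <- function(t) 0.5 / (4 * 0.1 * t + w^2) + 0.5 / (4 * 2 * t + w^2)
  cur <- new("CorrelationCurve", lagTimes = tau, G = Gfun(tau),
             nSamples = rep(1, length(tau)), species = c("a", "a"))
  tt <- transitionTime(cur, w)
  # independent oracle: bisection for Gfun(t) = Gfun(0)/2
  lo <- 1e-6; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (Gfun(mid) > Gfun(0) / 2) lo <- mid else hi <- mid
  }
  expect_lt(abs(tt@gammaD - lo) / lo, 0.005)
})

test_that("constant and non-decaying curves are rejected", {
  tau <- 10^seq(-4, 0, by = 0.1)
  flat <- new("CorrelationCurve", lagTimes = tau, G = rep(1, length(tau)),
              nSamples = rep(1, length(tau)), species = c("a", "a"))
  expect_error(transitionTime(flat, 0.25), "decay")
  expect_error(transitionTime(flat, -1), "positive")
})

test_that("fitting-free and fitted D agree in the noiseless limit", {
  for (D in c(0.1, 1, 2)) {
    surf <- closedFormSurface(D = D)
    fit <- fitNSpecies(surf, 1)
    tt <- transitionTime(surfaceCurve(surf), surf@waist)
    expect_lt(abs(diffusionCoef(tt) - diffusionCoef(fit)) /
              diffusionCoef(fit), 0.02)
  }
})

test_that("fit is invariant to species start permutation", {
  surf <- closedFormSurface()
  surf@G <- diffusionModel(surf@lagTimes, surf@spatialLags, 0.01,
                           c(0.3, 0.7), c(0.2, 3), 0.25)
  a <- fitNSpecies(surf, 2, init = list(offset = 0, A = c(0.5, 0.5),
                                        D = c(0.1, 5)))
  b <- fitNSpecies(surf, 2, init = list(offset = 0, A = c(0.5, 0.5),
                                        D = c(5, 0.1)))
  expect_equal(a@D, b@D, tolerance = 1e-6)
  expect_equal(a@amplitudes, b@amplitudes, tolerance = 1e-5)
})

test_that("segment profile of a uniform field shows no partner correlation", {
  g <- ScanGeometry()  # 50,000 lines
  species <- list(SpeciesSpec("kinase", 1, 1, 20, syntheticSpectrum("green")),
                  SpeciesSpec("cluster", 0, 5, 0.5, syntheticSpectrum("red"),
                              mobile = FALSE))
  st <- reorderBidirectional(simulateLineScan(species, g, seed = 31))
  fs <- stackFilters(st, list(syntheticSpectrum("green"),
                              syntheticSpectrum("red")),
                     labels = c("kinase", "cluster"))
  sp <- spatialCrossCorrelation(st, fs, maxDelta = 0.5, species = 1L)
  prof <- diffusionProfile(st, fs, sp$waist, nSegments = 20L)
  ok <- is.finite(prof@D)
  expect_gt(sum(ok), 10)
  expect_lt(sd(prof@D[ok]) / mean(prof@D[ok]), 0.5)  # CV < 50%
  expect_lt(abs(prof@correlation), 0.5)
  expect_error(diffusionProfile(st, fs, sp$waist, nSegments = 0L),
               "at least 1")
})
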