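## Filtered temporal / spatial correlation of line-scan photon streams.

.resolveFilter <- function(filter, species, nChannels) {
  if (is(filter, "SpectralFilterSet")) {
    if (is.character(species)) species <- match(species, filter@species)
    filter <- filter@filters[species, ]
  }
  if (length(filter) != nChannels)
    stop("filter length must equal the number of spectral channels")
  filter
}

#' Reorder a bidirectional line-scan stack
#'
#' Bidirectional acquisitions write odd-numbered lines in reversed pixel
#' order.  This reverses them back so that every line shares one spatial
#' orientation, and marks the stack as reordered.  Calling it twice is
#' an error; unidirectional stacks are returned unchanged.
#'
#' @param stack a \linkS4class{SpectralLineScanStack}.
#' @return the reordered stack.
#' @export
reorderBidirectional <- function(stack) {
  if (stack@reordered)
    stop("stack has already been reordered")
  if (!stack@geometry@bidirectional) return(stack)
  nL <- stack@geometry@nLines
  nP <- stack@geometry@nPixels
  odd <- seq(2L, nL, by = 2L)
  stack@counts[odd, , ] <- stack@counts[odd, nP:1L, , drop = FALSE]
  stack@reordered <- TRUE
  stack
}

.checkReordered <- function(stack) {
  if (stack@geometry@bidirectional && !stack@reordered)
    stop("bidirectional stack must be passed through reorderBidirectional() first")
}

#' Filtered temporal correlation on a multi-tau lag grid
#'
#' For every pixel column in \code{pixelRange}, forms the filtered
#' intensity series \code{F(t) = sum_j f_j I_j(t)} sampled at the line
#' period and computes the normalized correlation
#' \code{<F_a(t) F_b(t+tau)> / (<F_a> <F_b>) - 1} with symmetric
#' normalization (means over the overlapping window at each lag) on a
#' quasi-logarithmic multi-tau grid starting at one line period, then
#' averages the per-column correlations.  With \code{filterB} equal to
#' \code{filterA} this is the filtered autocorrelation; with distinct
#' filters, the cross-correlation between species.
#'
#' @param stack a reordered \linkS4class{SpectralLineScanStack}.
#' @param filterA per-channel weights of the first species (vector or
#'   \linkS4class{SpectralFilterSet} row).
#' @param filterB weights of the second species; defaults to
#'   \code{filterA} (autocorrelation).
#' @param pixelRange integer vector of pixel columns (default: all).
#' @param m multi-tau register size; m = 16 gives 8 lag points per
#'   octave.
#' @param maxLag largest lag in line periods; capped at nLines/4 and an
#'   error beyond it.
#' @param speciesA,speciesB labels/rows used when filters come from a
#'   \linkS4class{SpectralFilterSet}.
#' @return A \linkS4class{CorrelationCurve}.
#' @export
temporalCorrelation <- function(stack, filterA, filterB = NULL,
                                pixelRange = NULL, m = 16L,
                                maxLag = NULL, speciesA = 1L,
                                speciesB = 2L) {
  .checkReordered(stack)
  nC <- dim(stack@counts)[3]
  auto <- is.null(filterB)
  fa <- .resolveFilter(filterA, speciesA, nC)
  fb <- if (auto) fa else .resolveFilter(filterB, speciesB, nC)
  nL <- stack@geometry@nLines
  if (is.null(maxLag)) maxLag <- nL %/% 4L
  if (maxLag > nL / 4)
    stop("maxLag must not exceed nLines/4")
  if (is.null(pixelRange)) pixelRange <- seq_len(stack@geometry@nPixels)

  ia <- filteredIntensity(stack, fa)
  if (mean(ia[, pixelRange]) <= 0)
    stop("filtered intensity has non-positive mean; correlation undefined")
  ib <- if (auto) ia else filteredIntensity(stack, fb)

  mat <- if (auto) ia else cbind(ia[, pixelRange, drop = FALSE],
                                 ib[, pixelRange, drop = FALSE])
  np <- length(pixelRange)
  if (auto) {
    colsA <- pixelRange - 1L; colsB <- colsA
    res <- .cpp_multitau_pairs(mat, colsA, colsB, as.integer(m),
                               as.double(maxLag))
  } else {
    res <- .cpp_multitau_pairs(mat, seq_len(np) - 1L,
                               np + seq_len(np) - 1L, as.integer(m),
                               as.double(maxLag))
  }
  if (res$pairs_used == 0L)
    stop("all pixel columns had zero-mean filtered series")
  labA <- if (is.character(speciesA)) speciesA else paste0("species", speciesA)
  labB <- if (auto) labA
          else if (is.character(speciesB)) speciesB
          else paste0("species", speciesB)
  new("CorrelationCurve",
      lagTimes = res$lag * stack@geometry@linePeriod,
      G = res$G, nSamples = res$n, species = c(labA, labB))
}

#' Direct-sum reference correlator
#'
#' The O(N^2) textbook estimator of the fluctuation correlation at the
#' given integer lags, with the same symmetric normalization as the
#' multi-tau correlator but no lag-binning.  Intended as an independent
#' cross-check of the multi-tau estimator on short records.
#'
#' @param x,y numeric series (y defaults to x).
#' @param lags integer lags, in samples.
#' @return numeric vector of G values.
#' @export
directCorrelation <- function(x, y = x, lags) {
  n <- length(x)
  vapply(lags, function(k) {
    if (k >= n) return(NA_real_)
    t <- seq_len(n - k)
    mean(x[t] * y[t + k]) / (mean(x[t]) * mean(y[t + k])) - 1
  }, 0)
}

.fitGaussianProfile <- function(delta, G) {
  keep <- is.finite(G)
  delta <- delta[keep]; G <- G[keep]
  if (length(delta) < 5L)
    stop("at least 5 spatial lag points are required")
  ord <- order(delta)
  delta <- delta[ord]; G <- G[ord]
  if (G[1] <= 0 || mean(G[seq_len(2)]) <= mean(G[seq(length(G) - 1, length(G))]))
    stop("spatial profile does not decay; no Gaussian fit possible")
  # start values by moments on the positive part
  gpos <- pmax(G, 1e-12 * max(G))
  w0 <- sqrt(sum(gpos * delta^2) / sum(gpos)) * sqrt(2)
  if (!is.finite(w0) || w0 <= 0) w0 <- max(delta) / 2
  # the constant c absorbs the small negative finite-record bias of the
  # symmetric normalization, which would otherwise narrow the Gaussian
  fit <- minpack.lm::nlsLM(
    G ~ a * exp(-delta^2 / w^2) + c,
    start = list(a = max(G), w = w0, c = 0),
    lower = c(0, 1e-4, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["w", "Std. Error"],
                 error = function(e) NA_real_)
  list(amplitude = unname(co["a"]), waist = unname(co["w"]), waistSe = se)
}

#' Spatial cross-correlation and beam-waist recovery
#'
#' Correlates the filtered intensities of pixel pairs separated by
#' spatial lag delta at the minimal temporal lag (one line period, the
#' closest observable proxy for zero lag with a single scanned beam).
#' Because the 2D diffusion model at t -> 0 gives
#' \code{G(0, delta) ~ exp(-delta^2 / w^2)}, a Gaussian fit of the
#' profile recovers the beam waist directly --- equivalently
#' \code{w = FWHM / (2 sqrt(ln 2))} --- with no reference-dye
#' calibration.
#'
#' @param stack a reordered \linkS4class{SpectralLineScanStack}.
#' @param filter per-channel species weights (or filter set).
#' @param maxDelta largest spatial lag in micrometres; must be below
#'   half the line length.
#' @param species filter-set row when applicable.
#' @return list with \code{delta} (um), \code{G}, \code{waist} (um),
#'   \code{waistSe} and \code{amplitude}.
#' @export
spatialCrossCorrelation <- function(stack, filter, maxDelta = 0.6,
                                    species = 1L) {
  .checkReordered(stack)
  nC <- dim(stack@counts)[3]
  f <- .resolveFilter(filter, species, nC)
  mat <- filteredIntensity(stack, f)
  .spatialProfile(mat, stack@geometry, maxDelta)
}

.spatialProfile <- function(mat, geom, maxDelta) {
  if (maxDelta >= geom@lineLength / 2)
    stop("maxDelta must be smaller than half the line length")
  maxPx <- floor(maxDelta / geom@pixelSize)
  deltas <- 0:maxPx
  if (length(deltas) < 5L)
    stop("fewer than 5 spatial lag points; increase maxDelta")
  G <- .cpp_spatial_profile(mat, as.integer(deltas), 1L)
  deltaUm <- deltas * geom@pixelSize
  fit <- .fitGaussianProfile(deltaUm, G)
  list(delta = deltaUm, G = G, waist = fit$waist, waistSe = fit$waistSe,
       amplitude = fit$amplitude)
}

#' Assemble the spatio-temporal correlation surface
#'
#' Computes G(t, delta) on the multi-tau temporal grid for each spatial
#' pixel separation in \code{deltaPx}, averaging per-column-pair
#' correlations (both orientations), and embeds the beam waist recovered
#' by \code{\link{spatialCrossCorrelation}} so that no reference-dye
#' calibration is needed.  The delta = 0 slice equals the output of
#' \code{\link{temporalCorrelation}} on the same columns.
#'
#' @param stack a reordered \linkS4class{SpectralLineScanStack}.
#' @param filter per-channel species weights (or filter set).
#' @param deltaPx integer spatial lags in pixels (must include 0).
#' @param pixelRange pixel columns to use (default: all).
#' @param colStride stride over starting columns for off-zero spatial
#'   lags (correlation-level averaging cost control).
#' @param m multi-tau register size.
#' @param maxLag largest temporal lag in line periods.
#' @param species filter-set row when applicable.
#' @param maxDelta passed to \code{\link{spatialCrossCorrelation}}.
#' @return A \linkS4class{CorrelationSurface}.
#' @export
assembleSurface <- function(stack, filter, deltaPx = seq(0, 24, by = 3),
                            pixelRange = NULL, colStride = 2L, m = 16L,
                            maxLag = NULL, species = 1L, maxDelta = 0.6) {
  .checkReordered(stack)
  geom <- stack@geometry
  nC <- dim(stack@counts)[3]
  f <- .resolveFilter(filter, species, nC)
  if (deltaPx[1] != 0L) stop("deltaPx must include 0 as its first element")
  if (is.null(pixelRange)) pixelRange <- seq_len(geom@nPixels)
  nL <- geom@nLines
  if (is.null(maxLag)) maxLag <- nL %/% 4L

  mat <- filteredIntensity(stack, f)
  if (mean(mat[, pixelRange]) <= 0)
    stop("filtered intensity has non-positive mean; correlation undefined")

  Gcols <- list()
  lag <- NULL; nsamp <- NULL
  for (j in seq_along(deltaPx)) {
    d <- deltaPx[j]
    if (d == 0L) {
      cols <- pixelRange - 1L
      res <- .cpp_multitau_pairs(mat, cols, cols, as.integer(m),
                                 as.double(maxLag))
    } else {
      starts <- pixelRange[seq(1L, length(pixelRange), by = colStride)]
      starts <- starts[starts + d <= max(pixelRange)]
      if (length(starts) == 0L) { Gcols[[j]] <- NULL; next }
      ia <- c(starts - 1L, starts - 1L + d)
      ib <- c(starts - 1L + d, starts - 1L)
      res <- .cpp_multitau_pairs(mat, ia, ib, as.integer(m),
                                 as.double(maxLag))
    }
    if (is.null(lag)) { lag <- res$lag; nsamp <- res$n }
    Gcols[[j]] <- res$G
  }
  keep <- !vapply(Gcols, is.null, TRUE)
  G <- do.call(cbind, Gcols[keep])

  sp <- .spatialProfile(mat, geom, maxDelta)
  new("CorrelationSurface", lagTimes = lag * geom@linePeriod,
      spatialLags = deltaPx[keep] * geom@pixelSize, G = G,
      nSamples = nsamp, waist = sp$waist,
      waistSe = if (is.na(sp$waistSe)) numeric(0) else sp$waistSe,
      segment = "line-average")
}

#' Split a line scan into contiguous segments
#'
#' Splits the pixel axis into \code{nSegments} contiguous segments of
#' \code{floor(nPixels / nSegments)} pixels each, centred on the line
#' with the remainder trimmed equally from both ends (256 pixels in 20
#' segments gives 12-pixel segments, 8 pixels trimmed at each end, each
#' segment ~250 nm --- the equivalent of 20 raw single-point FCS
#' measurements).
#'
#' @param stack a \linkS4class{SpectralLineScanStack}.
#' @param nSegments number of segments (>= 1, <= nPixels, and the
#'   segments must jointly cover at least half the line).
#' @return list with \code{segments} (list of per-segment
#'   \linkS4class{SpectralLineScanStack} views), \code{pixelRanges},
#'   and \code{centers} (um along the line).
#' @export
segmentLine <- function(stack, nSegments) {
  geom <- stack@geometry
  nP <- geom@nPixels
  nSegments <- as.integer(nSegments)
  if (nSegments < 1L) stop("nSegments must be at least 1")
  if (nSegments > nP) stop("nSegments must not exceed the pixel count")
  segLen <- nP %/% nSegments
  if (nSegments * segLen < nP / 2)
    stop("segments would cover less than half the line")
  trim <- (nP - nSegments * segLen) %/% 2L
  ranges <- lapply(seq_len(nSegments) - 1L,
                   function(s) trim + s * segLen + seq_len(segLen))
  segs <- lapply(ranges, function(r) {
    g <- geom
    g@nPixels <- length(r)
    g@lineLength <- length(r) * g@pixelSize
    SpectralLineScanStack(stack@counts[, r, , drop = FALSE], g,
                          stack@channelBounds, stack@provenance,
                          reordered = stack@reordered)
  })
  centers <- vapply(ranges, function(r) (mean(r) - 0.5) * geom@pixelSize, 0)
  list(segments = segs, pixelRanges = ranges, centers = centers)
}

#' Write a correlation curve as TSV
#'
#' @param curve a \linkS4class{CorrelationCurve}.
#' @param path file path.
#' @param provenance optional '#' header lines.
#' @return the path, invisibly.
#' @export
writeCurveTSV <- function(curve, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in provenance) writeLines(paste0("# ", p), con)
  d <- data.frame(lag_s = curve@lagTimes, G = curve@G,
                  n = curve@nSamples)
  write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
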