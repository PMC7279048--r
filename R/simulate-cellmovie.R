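## Synthetic cell time-lapse movies with known ground truth.

.ellipseRadial <- function(shape, center, radii) {
  y <- matrix(seq_len(shape[1]), shape[1], shape[2])
  x <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  sqrt(((y - center[1]) / radii[1])^2 + ((x - center[2]) / radii[2])^2)
}

#' Simulate a cell-shaped time-lapse movie
#'
#' Renders an elliptical cell on a dark background.  Per frame and
#' channel, the channel's total intensity is split between a peripheral
#' membrane shell (the outer \code{shellFraction} of the normalized
#' radius) and the cytosol core according to the channel's membrane
#' fraction time course, spread uniformly within each compartment.
#' Optional punctate clusters (uniform disks at fixed random positions
#' inside the cell) appear at the channel's onset frame.  Poisson photon
#' noise and additive Gaussian read noise are applied last.
#'
#' @param spec a \linkS4class{CellMovieSpec}.
#' @param seed integer seed.
#' @return A list with elements \code{movie} (a
#'   \linkS4class{TimeLapseStack}) and \code{truth}: per-channel
#'   per-frame membrane fraction and total intensity, cluster
#'   coordinates, and the compartment masks used.
#' @export
simulateCellMovie <- function(spec, seed = 1L) {
  validObject(spec)
  set.seed(seed)
  sh <- spec@imageShape
  rr <- .ellipseRadial(sh, spec@center, spec@radii)
  footprint <- rr <= 1
  membrane <- footprint & rr >= 1 - spec@shellFraction
  cytosol <- footprint & !membrane
  nMem <- sum(membrane); nCyt <- sum(cytosol)
  if (nMem == 0L || nCyt == 0L)
    stop("degenerate compartments; adjust radii or shellFraction")

  nF <- spec@nFrames; nC <- length(spec@channels)
  frames <- array(0, c(nF, sh[1], sh[2], nC))
  truth <- list(membraneFraction = matrix(NA_real_, nF, nC),
                totalIntensity = matrix(NA_real_, nF, nC),
                clusters = vector("list", nC),
                footprint = footprint, membrane = membrane,
                cytosol = cytosol)

  for (c in seq_len(nC)) {
    ch <- spec@channels[[c]]
    # cluster centres drawn once, kept fixed over time
    if (ch$nClusters > 0L && !is.na(ch$onsetFrame)) {
      margin <- ch$clusterRadius + 1
      ok <- which(rr <= 1 - margin / min(spec@radii))
      if (length(ok) < ch$nClusters)
        stop("cell too small for the requested clusters")
      idx <- sample(ok, ch$nClusters)
      cy <- (idx - 1L) %% sh[1] + 1L
      cx <- (idx - 1L) %/% sh[1] + 1L
      truth$clusters[[c]] <- data.frame(y = cy, x = cx,
                                        radius = ch$clusterRadius,
                                        amplitude = ch$clusterAmplitude,
                                        onset = ch$onsetFrame)
      clusterMask <- matrix(FALSE, sh[1], sh[2])
      for (k in seq_along(cy)) {
        dy <- matrix(seq_len(sh[1]) - cy[k], sh[1], sh[2])
        dx <- matrix(seq_len(sh[2]) - cx[k], sh[1], sh[2], byrow = TRUE)
        clusterMask <- clusterMask | (dy^2 + dx^2 <= ch$clusterRadius^2)
      }
    } else clusterMask <- NULL

    for (t in seq_len(nF)) {
      img <- matrix(0, sh[1], sh[2])
      mf <- ch$membraneFraction[t]
      tot <- ch$totalIntensity[t]
      img[membrane] <- tot * mf / nMem
      img[cytosol] <- tot * (1 - mf) / nCyt
      if (!is.null(clusterMask) && t >= ch$onsetFrame)
        img[clusterMask] <- img[clusterMask] + ch$clusterAmplitude
      truth$membraneFraction[t, c] <- mf
      truth$totalIntensity[t, c] <- sum(img)
      frames[t, , , c] <- img
    }
  }

  if (spec@photonScale > 0) {
    n <- length(frames)
    frames[] <- rpois(n, spec@photonScale * as.vector(frames)) /
      spec@photonScale
  }
  if (spec@gaussianSd > 0) {
    frames[] <- frames + rnorm(length(frames), 0, spec@gaussianSd)
    frames[frames < 0] <- 0
  }

  movie <- TimeLapseStack(frames, spec@frameInterval,
                          vapply(spec@channels, function(ch) ch$label, ""))
  list(movie = movie, truth = truth)
}
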