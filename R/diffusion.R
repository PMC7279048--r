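## 2D n-species free-diffusion fitting and the fitting-free
## transition-time estimator.

#' Evaluate the 2D n-species free-diffusion correlation model
#'
#' \deqn{G(t, \delta) = G_{offset} + \sum_i A_i \frac{1}{4 D_i t + w^2}
#'   \exp\!\left(-\frac{\delta^2}{4 D_i t + w^2}\right)}
#' with temporal lag t (s), spatial lag delta (um), amplitudes A_i,
#' diffusion coefficients D_i (um^2/s) and beam waist w (um).
#'
#' @param t numeric vector of temporal lags (s).
#' @param delta numeric vector of spatial lags (um).
#' @param offset baseline.
#' @param A per-species amplitudes.
#' @param D per-species diffusion coefficients (um^2/s).
#' @param w beam waist (um).
#' @return matrix [length(t), length(delta)].
#' @export
diffusionModel <- function(t, delta, offset, A, D, w) {
  G <- matrix(offset, length(t), length(delta))
  for (i in seq_along(A)) {
    denom <- 4 * D[i] * t + w^2            # [t]
    G <- G + A[i] * exp(-outer(1 / denom, delta^2)) / denom
  }
  G
}

.surfaceResiduals <- function(par, n, tt, dd, G, w, wts) {
  offset <- par[1]
  A <- par[1 + seq_len(n)]
  D <- exp(par[1 + n + seq_len(n)])
  pred <- diffusionModel(tt, dd, offset, A, D, w)
  as.vector((pred - G) * wts)
}

#' Fit the n-species 2D free-diffusion model to a correlation surface
#'
#' Weighted least squares over the full (t, delta) surface with the beam
#' waist held fixed at the spatial-cross-correlation estimate embedded
#' in the surface.  Fitting uses Levenberg-Marquardt with multi-start
#' initialization over per-species diffusion coefficients
#' {0.01, 0.1, 1, 10} um^2/s (all ascending combinations), amplitudes
#' seeded from G at the smallest lags times w^2, and the offset from the
#' correlation tail mean.  Species are reported in ascending D order.
#'
#' @param surface a \linkS4class{CorrelationSurface} with at least 10
#'   temporal and 5 spatial lags.
#' @param nSpecies number of diffusing species (1..3).
#' @param init optional list(offset, A, D) overriding the multi-start.
#' @param weights optional weight matrix matching \code{surface@G};
#'   defaults to sqrt(samples per lag), constant across delta.
#' @return A \linkS4class{DiffusionFitResult}.
#' @export
fitNSpecies <- function(surface, nSpecies = 1L, init = NULL,
                        weights = NULL) {
  nSpecies <- as.integer(nSpecies)
  if (nSpecies < 1L || nSpecies > 3L)
    stop("nSpecies must be between 1 and 3")
  tt <- surface@lagTimes
  dd <- surface@spatialLags
  if (length(tt) < 10L) stop("at least 10 temporal lags are required")
  if (length(dd) < 5L) stop("at least 5 spatial lags are required")
  w <- surface@waist
  if (length(w) == 0L || w <= 0) stop("surface must carry a beam waist")
  G <- surface@G
  wts <- if (is.null(weights)) {
    base <- sqrt(surface@nSamples / max(surface@nSamples))
    matrix(base, length(tt), length(dd))
  } else weights

  offset0 <- mean(G[seq(max(1, length(tt) - 4), length(tt)), 1])
  amp0 <- max(G[1, 1] - offset0, 1e-8) * w^2

  starts <- if (!is.null(init)) {
    list(c(init$offset, init$A, log(init$D)))
  } else {
    Dgrid <- c(0.01, 0.1, 1, 10)
    combos <- if (nSpecies == 1L) as.list(Dgrid) else {
      cc <- utils::combn(Dgrid, nSpecies, simplify = FALSE)
      cc
    }
    lapply(combos, function(D0)
      c(offset0, rep(amp0 / nSpecies, nSpecies), log(D0)))
  }

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = .surfaceResiduals, n = nSpecies, tt = tt, dd = dd,
        G = G, w = w, wts = wts,
        lower = c(-Inf, rep(0, nSpecies), rep(log(1e-6), nSpecies)),
        upper = c(Inf, rep(Inf, nSpecies), rep(log(1e4), nSpecies)),
        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("diffusion fit did not converge from any start")

  par <- best$par
  offset <- par[1]
  A <- par[1 + seq_len(nSpecies)]
  D <- exp(par[1 + nSpecies + seq_len(nSpecies)])
  ord <- order(D)
  A <- A[ord]; D <- D[ord]
  pred <- diffusionModel(tt, dd, offset, A, D, w)
  rms <- sqrt(mean((pred - G)^2))
  se <- tryCatch({
    cv <- diag(vcov(best))
    list(offset = sqrt(cv[1]), A = sqrt(cv[1 + seq_len(nSpecies)])[ord],
         logD = sqrt(cv[1 + nSpecies + seq_len(nSpecies)])[ord])
  }, error = function(e) list())
  new("DiffusionFitResult", offset = offset, amplitudes = A, D = D,
      waist = w, residualRms = rms, se = se, nSpecies = nSpecies)
}

#' Fitting-free transition-time diffusion estimate
#'
#' Smooths the correlation curve with a cubic smoothing spline in
#' log-lag space, extrapolates to zero lag to estimate G(0), and finds
#' the lag gammaD at which the smoothed curve crosses G(0)/2 (monotone
#' interpolation between the bracketing grid points).  gammaD is the
#' transition time of the molecule across the detection volume and
#' yields \code{D = w^2 / (4 gammaD)} with no assumption on the number
#' of diffusing components or the diffusion mode.
#'
#' Because the lag grid is logarithmic, G(0) is evaluated at a pseudo
#' lag of one tenth of the minimal lag rather than at exactly zero.
#'
#' @param curve a decaying \linkS4class{CorrelationCurve}.
#' @param w beam waist (um).
#' @param spar smoothing parameter for \code{\link[stats]{smooth.spline}};
#'   NULL (default) selects it by generalized cross-validation.
#' @return A \linkS4class{TransitionTimeResult}.
#' @export
transitionTime <- function(curve, w, spar = NULL) {
  if (w <= 0) stop("waist must be positive")
  tau <- curve@lagTimes
  G <- curve@G
  if (length(tau) < 10L) stop("too few lags for spline smoothing")
  k <- max(2L, floor(length(G) / 10))
  if (!(mean(G[seq_len(k)]) > mean(G[seq(length(G) - k + 1, length(G))])))
    stop("correlation curve does not decay; transition time undefined")
  lt <- log10(tau)
  sfit <- if (is.null(spar)) smooth.spline(lt, G, cv = FALSE)
          else smooth.spline(lt, G, spar = spar)
  l0 <- log10(tau[1] / 10)
  G0 <- predict(sfit, l0)$y
  if (G0 <= 0) stop("extrapolated G(0) is non-positive")
  half <- G0 / 2
  sm <- predict(sfit, lt)$y
  below <- which(sm <= half)
  above <- which(sm > half)
  if (length(below) == 0L || length(above) == 0L)
    stop("no half-amplitude crossing within the lag range")
  i <- below[below > min(above)][1]
  if (is.na(i) || i < 2L)
    stop("no half-amplitude crossing within the lag range")
  # linear interpolation in log-lag between the bracketing grid points
  f <- (sm[i - 1] - half) / (sm[i - 1] - sm[i])
  lgamma <- lt[i - 1] + f * (lt[i] - lt[i - 1])
  gammaD <- 10^lgamma
  new("TransitionTimeResult", G0 = G0, gammaD = gammaD,
      D = w^2 / (4 * gammaD), waist = w,
      spar = sfit$spar)
}

#' Per-segment diffusion vs partner-intensity profile
#'
#' Splits the line into segments, runs the fitting-free transition-time
#' estimator on each segment's filtered autocorrelation of the primary
#' (kinase) species, pairs the per-segment diffusion coefficients with
#' the mean filtered intensity of the partner (clustered) species in the
#' same segment, and reports their Pearson correlation.  Segments whose
#' curves do not decay (or fail the estimator) are excluded, not
#' imputed; the exclusion count is part of the result.
#'
#' @param stack a reordered \linkS4class{SpectralLineScanStack}.
#' @param filters a \linkS4class{SpectralFilterSet} with at least two
#'   species.
#' @param w beam waist (um).
#' @param nSegments number of line segments (default 20).
#' @param speciesA primary species whose diffusion is estimated (label
#'   or row).
#' @param speciesB partner species whose intensity marks cluster
#'   locations.
#' @param m,maxLag multi-tau parameters, as in
#'   \code{\link{temporalCorrelation}}.
#' @param spar optional spline smoothing parameter.
#' @return A \linkS4class{SegmentDiffusionProfile}.
#' @export
diffusionProfile <- function(stack, filters, w, nSegments = 20L,
                             speciesA = 1L, speciesB = 2L, m = 16L,
                             maxLag = NULL, spar = NULL) {
  nSegments <- as.integer(nSegments)
  if (nSegments < 1L) stop("nSegments must be at least 1")
  .checkReordered(stack)
  seg <- segmentLine(stack, nSegments)
  nC <- dim(stack@counts)[3]
  fa <- .resolveFilter(filters, speciesA, nC)
  fb <- .resolveFilter(filters, speciesB, nC)
  partner <- filteredIntensity(stack, fb)
  kinase <- filteredIntensity(stack, fa)  # computed once for all segments
  nL <- stack@geometry@nLines
  if (is.null(maxLag)) maxLag <- nL %/% 4L

  D <- rep(NA_real_, nSegments)
  pint <- rep(NA_real_, nSegments)
  for (s in seq_len(nSegments)) {
    r <- seg$pixelRanges[[s]]
    pint[s] <- mean(partner[, r])
    est <- tryCatch({
      res <- .cpp_multitau_pairs(kinase, r - 1L, r - 1L, as.integer(m),
                                 as.double(maxLag))
      if (res$pairs_used == 0L) stop("zero-mean segment")
      cur <- new("CorrelationCurve",
                 lagTimes = res$lag * stack@geometry@linePeriod,
                 G = res$G, nSamples = res$n,
                 species = c("kinase", "kinase"))
      transitionTime(cur, w, spar = spar)
    }, error = function(e) NULL)
    if (!is.null(est)) D[s] <- est@D
  }
  ok <- is.finite(D)
  excluded <- sum(!ok)
  corDI <- if (sum(ok) >= 3 && sd(D[ok]) > 0 && sd(pint[ok]) > 0)
    cor(D[ok], pint[ok]) else NA_real_
  new("SegmentDiffusionProfile", position = seg$centers, D = D,
      partnerIntensity = pint, correlation = corDI,
      excluded = as.integer(excluded))
}

#' Write a diffusion fit or segment profile as TSV
#'
#' @param x a \linkS4class{DiffusionFitResult},
#'   \linkS4class{TransitionTimeResult} or
#'   \linkS4class{SegmentDiffusionProfile}.
#' @param path file path.
#' @param provenance optional '#' header lines.
#' @return the path, invisibly.
#' @export
writeResultTSV <- function(x, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in provenance) writeLines(paste0("# ", p), con)
  d <- if (is(x, "DiffusionFitResult")) {
    data.frame(species = seq_len(x@nSpecies), A = x@amplitudes, D = x@D,
               offset = x@offset, waist = x@waist,
               residual_rms = x@residualRms)
  } else if (is(x, "TransitionTimeResult")) {
    data.frame(G0 = x@G0, gammaD_s = x@gammaD, D = x@D, waist = x@waist)
  } else if (is(x, "SegmentDiffusionProfile")) {
    data.frame(position_um = x@position, D = x@D,
               partner_intensity = x@partnerIntensity)
  } else stop("unsupported result type")
  write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
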