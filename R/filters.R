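## Statistical spectral filters for filtered FCS.

#' Compute spectral unmixing filters
#'
#' Builds per-species statistical filters from normalized reference
#' emission spectra and the mixed sample spectrum by weighted least
#' squares: \code{F = (M' W M)^-1 M' W}, with M the matrix whose columns
#' are the normalized reference spectra and W the diagonal inverse of
#' the mixed per-channel intensity (Poisson weighting: the variance of a
#' photon-count channel equals its mean).  The filters reproduce each
#' reference exactly (\code{F M = I}), and whenever the mixed spectrum
#' is an exact nonnegative combination of the references the filters of
#' all species sum to one in every channel.  Filters are not
#' renormalized after the solve.
#'
#' @param references list of \linkS4class{EmissionSpectrum} objects (or
#'   a matrix with one normalized spectrum per column), at least two,
#'   linearly independent.
#' @param mixed per-channel mean intensity of the sample; strictly
#'   positive wherever any reference is positive.
#' @param labels optional species labels.
#' @return A \linkS4class{SpectralFilterSet}.
#' @export
computeFilters <- function(references, mixed, labels = NULL) {
  if (is.list(references)) {
    if (is.null(labels)) labels <- paste0("species", seq_along(references))
    M <- vapply(references, function(s) s@probabilities,
                numeric(length(references[[1]]@probabilities)))
  } else {
    M <- as.matrix(references)
    if (is.null(labels)) labels <- paste0("species", seq_len(ncol(M)))
  }
  if (ncol(M) < 2L) stop("at least two reference spectra are required")
  if (length(mixed) != nrow(M))
    stop("mixed spectrum length must match the channel count")
  if (any(mixed < 0)) stop("mixed intensities must be nonnegative")
  live <- rowSums(abs(M)) > 0
  if (any(mixed[live] <= 0))
    stop("mixed spectrum must be strictly positive on channels where a reference is positive")
  M <- sweep(M, 2, colSums(M), "/")  # intensity-normalized spectra

  w <- ifelse(mixed > 0, 1 / mixed, 0)
  MtW <- t(M * w)                        # M' W
  A <- MtW %*% M
  if (rcond(A) < 1e-12)
    stop("reference spectra are collinear or singular")
  flt <- solve(A, MtW)
  rownames(flt) <- labels
  new("SpectralFilterSet", filters = flt, species = labels,
      references = M, mixed = as.numeric(mixed))
}

#' Compute filters from a line-scan stack
#'
#' Convenience wrapper: the mixed spectrum is the channel-mean count
#' spectrum of the stack itself, so filters are recalculated per sample
#' and then treated as constants in the correlation analysis.
#'
#' @param stack a \linkS4class{SpectralLineScanStack}.
#' @param references reference spectra, as in \code{\link{computeFilters}}.
#' @param labels optional species labels.
#' @return A \linkS4class{SpectralFilterSet}.
#' @export
stackFilters <- function(stack, references, labels = NULL) {
  mixed <- apply(stack@counts, 3, function(ch) mean(ch))
  computeFilters(references, mixed, labels)
}

#' Photon weight of a multiphoton dwell
#'
#' Under single-photon-counting detection a dwell registering n photons
#' contributes n times the filter weight of its channel: the filter is
#' scaled by the count value so multiphoton pixels are weighted
#' accordingly.
#'
#' @param filterValue filter weight of the channel.
#' @param count photon count of the dwell (nonnegative integer).
#' @return \code{filterValue * count} (0 for empty dwells).
#' @export
photonWeight <- function(filterValue, count) {
  if (any(count < 0)) stop("counts must be nonnegative")
  filterValue * count
}

#' Species-filtered intensity matrix
#'
#' Applies one species' filter across spectral channels, weighting each
#' dwell's counts by the channel filter values, and returns the filtered
#' intensity per (line, pixel).
#'
#' @param stack a \linkS4class{SpectralLineScanStack}.
#' @param filter numeric vector of per-channel filter weights, or a
#'   \linkS4class{SpectralFilterSet} plus \code{species}.
#' @param species species label or row index when \code{filter} is a
#'   filter set.
#' @return numeric matrix [nLines, nPixels].
#' @export
filteredIntensity <- function(stack, filter, species = 1L) {
  if (is(filter, "SpectralFilterSet")) {
    if (is.character(species)) species <- match(species, filter@species)
    filter <- filter@filters[species, ]
  }
  d <- dim(stack@counts)
  if (length(filter) != d[3])
    stop("filter length must equal the number of spectral channels")
  # accumulate channel by channel to keep peak memory at one channel copy
  m <- matrix(0, d[1], d[2])
  for (ch in seq_len(d[3]))
    if (filter[ch] != 0) m <- m + filter[ch] * stack@counts[, , ch]
  m
}

#' Read / write reference spectra as TSV
#'
#' Two data columns (channel lower and upper bound in nm) plus one
#' probability column; lines starting with '#' are treated as header.
#'
#' @param path file path.
#' @return \code{readSpectrumTSV}: an \linkS4class{EmissionSpectrum}.
#' @export
readSpectrumTSV <- function(path) {
  d <- read.delim(path, comment.char = "#")
  if (!all(c("lower_nm", "upper_nm", "probability") %in% names(d)))
    stop("spectrum TSV needs columns lower_nm, upper_nm, probability")
  EmissionSpectrum(cbind(d$lower_nm, d$upper_nm), d$probability)
}

#' @rdname readSpectrumTSV
#' @param spectrum an \linkS4class{EmissionSpectrum}.
#' @param comment optional provenance comment written as '#' header.
#' @export
writeSpectrumTSV <- function(spectrum, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  d <- data.frame(lower_nm = spectrum@channelBounds[, 1],
                  upper_nm = spectrum@channelBounds[, 2],
                  probability = spectrum@probabilities)
  write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a filter set as TSV with provenance header
#'
#' @param filters a \linkS4class{SpectralFilterSet}.
#' @param path file path.
#' @param provenance optional character lines for the '#' header.
#' @return the path, invisibly.
#' @export
writeFilterTSV <- function(filters, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in provenance) writeLines(paste0("# ", p), con)
  d <- data.frame(species = filters@species, filters@filters)
  names(d)[-1] <- paste0("ch", seq_len(ncol(filters@filters)))
  write.table(d, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
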