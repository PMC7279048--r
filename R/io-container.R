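## Self-describing binary container for line-scan photon-count stacks.
##
## Layout: the 8-byte magic "LSCSTACK", a newline, a 4-byte little-endian
## header length, a JSON header (schema version, array dims, geometry,
## channel bounds, provenance), then the counts as unsigned bytes in
## column-major [line, pixel, channel] order.  Replaces the vendor
## acquisition container with a documented, dependency-light format.

.LSC_MAGIC <- "LSCSTACK"
.LSC_SCHEMA <- 1L

#' Write / read a line-scan stack container
#'
#' Lossless round trip of counts, geometry, channel bounds and
#' provenance.  Counts are stored as unsigned 8-bit integers.
#'
#' @param stack a \linkS4class{SpectralLineScanStack}.
#' @param path file path (conventionally .lsc).
#' @return \code{writeLineScan}: the path, invisibly;
#'   \code{readLineScan}: a \linkS4class{SpectralLineScanStack}.
#' @export
writeLineScan <- function(stack, path) {
  g <- stack@geometry
  prov <- stack@provenance
  prov$totals <- NULL; prov$tracks <- NULL  # arrays: not serialized
  header <- list(
    schema_version = .LSC_SCHEMA,
    dims = dim(stack@counts),
    dtype = "uint8",
    geometry = list(line_length_um = g@lineLength, n_pixels = g@nPixels,
                    pixel_size_um = g@pixelSize,
                    pixel_dwell_s = g@pixelDwell,
                    line_period_s = g@linePeriod, n_lines = g@nLines,
                    bidirectional = g@bidirectional),
    channel_bounds_nm = unname(apply(stack@channelBounds, 1, c,
                                     simplify = FALSE)),
    reordered = stack@reordered,
    provenance = c(prov, list(
      tool = paste0("lineFSCS ", as.character(packageVersion("lineFSCS"))),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))))
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE,
                                      digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(.LSC_MAGIC, "\n")), con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  writeBin(as.raw(stack@counts), con)
  invisible(path)
}

#' @rdname writeLineScan
#' @export
readLineScan <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(.LSC_MAGIC) + 1L))
  if (!identical(magic, paste0(.LSC_MAGIC, "\n")))
    stop("not a line-scan container (bad magic)")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(hlen) == 0L || hlen <= 0L) stop("truncated container header")
  hraw <- readBin(con, "raw", hlen)
  if (length(hraw) < hlen) stop("truncated container header")
  header <- jsonlite::fromJSON(rawToChar(hraw), simplifyVector = TRUE)
  if (is.null(header$schema_version) ||
      header$schema_version != .LSC_SCHEMA)
    stop(sprintf("unsupported container schema version '%s' (supported: %d)",
                 header$schema_version, .LSC_SCHEMA))
  if (is.null(header$geometry))
    stop("container header is missing the scan geometry")
  d <- header$dims
  n <- prod(d)
  bytes <- readBin(con, "raw", n)
  if (length(bytes) < n) stop("truncated container payload")
  counts <- array(as.integer(bytes), dim = d)
  g <- header$geometry
  geom <- ScanGeometry(g$line_length_um, g$n_pixels, g$pixel_size_um,
                       g$pixel_dwell_s, g$line_period_s, g$n_lines,
                       g$bidirectional)
  cb <- header$channel_bounds_nm
  if (is.list(cb)) cb <- do.call(rbind, cb)
  prov <- header$provenance
  if (is.null(prov)) prov <- list()
  SpectralLineScanStack(counts, geom, cb, provenance = as.list(prov),
                        reordered = isTRUE(header$reordered))
}

#' Write / read a time-lapse hyperstack as multi-page TIFF
#'
#' Frames are written as 32-bit float TIFF pages in frame-major order
#' with channels as samples per pixel (up to 4; more channels fall back
#' to one page per frame-channel pair).  Intensities are scaled into
#' [0, 1] by a power-of-two scale recorded, with the frame interval,
#' channel names and axis order, in a JSON sidecar (path + ".json"), so
#' integer-valued data round-trip exactly.
#'
#' @param stack a \linkS4class{TimeLapseStack}.
#' @param path TIFF file path.
#' @return \code{writeHyperstack}: the path; \code{readHyperstack}: a
#'   \linkS4class{TimeLapseStack}.
#' @export
writeHyperstack <- function(stack, path) {
  d <- dim(stack@frames)
  mx <- max(stack@frames, 1e-12)
  # TIFF samples are quantized to 32-bit integers over [0, 1]; integer-
  # valued movies (photon counts) use the quantizer itself as the scale
  # so they round-trip exactly, others are quantized at ~2^-32 relative
  integerData <- mx < 2^31 &&
    max(abs(stack@frames - round(stack@frames))) == 0
  scale <- if (integerData) 2^32 - 1 else 2^ceiling(log2(mx))
  # 1- and 3-sample pages are valid TIFF photometric layouts; other
  # channel counts go one page per (frame, channel)
  interleaved <- d[4] %in% c(1L, 3L)
  pages <- if (interleaved) {
    lapply(seq_len(d[1]), function(t) {
      pg <- stack@frames[t, , , , drop = FALSE] / scale
      array(pg, d[2:4])
    })
  } else {
    unlist(lapply(seq_len(d[1]), function(t)
      lapply(seq_len(d[4]), function(c)
        matrix(stack@frames[t, , , c] / scale, d[2], d[3]))),
      recursive = FALSE)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(axis_order = "TYXC", n_frames = d[1], height = d[2],
               width = d[3], n_channels = d[4], scale = scale,
               integer_data = integerData, interleaved = interleaved,
               frame_interval_s = stack@frameInterval,
               channel_names = stack@channelNames)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeHyperstack
#' @export
readHyperstack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("ragged multi-page TIFF: inconsistent page shapes")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    d <- c(meta$n_frames, meta$height, meta$width, meta$n_channels)
    frames <- array(0, d)
    if (isTRUE(meta$interleaved)) {
      for (t in seq_len(d[1])) {
        pg <- pages[[t]]
        if (length(dim(pg)) == 2L) dim(pg) <- c(dim(pg), 1L)
        frames[t, , , ] <- pg
      }
    } else {
      k <- 1L
      for (t in seq_len(d[1])) for (c in seq_len(d[4])) {
        frames[t, , , c] <- pages[[k]]; k <- k + 1L
      }
    }
    frames <- frames * meta$scale
    if (isTRUE(meta$integer_data)) frames <- round(frames)
    TimeLapseStack(frames, meta$frame_interval_s, meta$channel_names)
  } else {
    # plain TIFF: pages are frames, samples (if any) are channels
    p1 <- pages[[1]]
    nc <- if (length(dim(p1)) == 3L) dim(p1)[3] else 1L
    d <- c(length(pages), dim(p1)[1], dim(p1)[2], nc)
    frames <- array(0, d)
    for (t in seq_along(pages)) {
      pg <- pages[[t]]
      if (length(dim(pg)) == 2L) dim(pg) <- c(dim(pg), 1L)
      frames[t, , , ] <- pg
    }
    TimeLapseStack(frames, 1)
  }
}

#' Write a cell-movie ground-truth table as TSV
#'
#' @param truth the truth record returned by
#'   \code{\link{simulateCellMovie}}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeTruthTSV <- function(truth, path) {
  nF <- nrow(truth$membraneFraction)
  nC <- ncol(truth$membraneFraction)
  d <- data.frame(frame = rep(seq_len(nF), nC),
                  channel = rep(seq_len(nC), each = nF),
                  membrane_fraction = as.vector(truth$membraneFraction),
                  total_intensity = as.vector(truth$totalIntensity))
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
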