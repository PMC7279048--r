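## Confocal image quantification: cluster STD traces, kymographs, Ca2+
## fold statistics, Otsu gating, radial masks, translocation, Pearson
## colocalization.  Image coordinates are 1-based [y, x], frames stored
## as [frame, y, x, channel].

.getChannel <- function(stack, channel) {
  if (is.character(channel)) {
    channel <- match(channel, stack@channelNames)
    if (is.na(channel)) stop("unknown channel label")
  }
  stack@frames[, , , channel, drop = TRUE]
}

#' Otsu threshold of an image
#'
#' Global histogram threshold maximizing between-class variance,
#' computed on a 256-bin histogram over the intensity range.
#'
#' @param x numeric matrix or vector of intensities.
#' @param nbins number of histogram bins (default 256).
#' @return the threshold value; pixels strictly above it are foreground.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!is.finite(rng[1]) || rng[1] == rng[2])
    stop("Otsu threshold is undefined for a constant image")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sigma2 <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- -Inf
  mids[which.max(sigma2)]
}

#' Per-frame ROI standard-deviation trace
#'
#' The population standard deviation (divide by n) of the pixel
#' intensities inside a rectangular ROI, per frame.  A rising trace
#' reports the appearance of intensity clusters inside the ROI.
#'
#' @param stack a \linkS4class{TimeLapseStack}.
#' @param roi integer vector c(y1, y2, x1, x2), 1-based inclusive.
#' @param channel channel index or label.
#' @return numeric vector, one SD per frame.
#' @export
roiStdTrace <- function(stack, roi, channel = 1L) {
  d <- dim(stack@frames)
  if (length(roi) != 4L) stop("roi must be c(y1, y2, x1, x2)")
  if (roi[1] < 1 || roi[2] > d[2] || roi[3] < 1 || roi[4] > d[3] ||
      roi[2] < roi[1] || roi[4] < roi[3])
    stop("roi must be a nonempty rectangle inside the frame")
  ch <- .getChannel(stack, channel)
  vapply(seq_len(d[1]), function(t) {
    px <- ch[t, roi[1]:roi[2], roi[3]:roi[4]]
    sqrt(mean((px - mean(px))^2))
  }, 0)
}

#' Kymograph along a line
#'
#' Intensity along a straight line (rounded to nearest pixels, averaged
#' over a perpendicular width) per frame; rows are positions along the
#' line, columns are time points.
#'
#' @param stack a \linkS4class{TimeLapseStack}.
#' @param line numeric c(y0, x0, y1, x1), endpoints in pixels.
#' @param width averaging width in pixels (odd; default 1).
#' @param channel channel index or label.
#' @return numeric matrix [position, time].
#' @export
kymograph <- function(stack, line, width = 1L, channel = 1L) {
  d <- dim(stack@frames)
  if (length(line) != 4L) stop("line must be c(y0, x0, y1, x1)")
  len <- sqrt((line[3] - line[1])^2 + (line[4] - line[2])^2)
  if (len < 1) stop("degenerate line")
  n <- ceiling(len) + 1L
  tpar <- seq(0, 1, length.out = n)
  ys <- line[1] + tpar * (line[3] - line[1])
  xs <- line[2] + tpar * (line[4] - line[2])
  # unit normal for width averaging
  nyx <- c(-(line[4] - line[2]), line[3] - line[1]) / len
  offs <- seq(-(width - 1) / 2, (width - 1) / 2)
  ch <- .getChannel(stack, channel)
  if (length(dim(ch)) == 2L) dim(ch) <- c(1L, dim(ch))
  out <- matrix(NA_real_, n, d[1])
  for (t in seq_len(d[1])) {
    vals <- vapply(seq_len(n), function(i) {
      acc <- 0; cnt <- 0
      for (o in offs) {
        yy <- round(ys[i] + o * nyx[1]); xx <- round(xs[i] + o * nyx[2])
        if (yy >= 1 && yy <= d[2] && xx >= 1 && xx <= d[3]) {
          acc <- acc + ch[t, yy, xx]; cnt <- cnt + 1
        }
      }
      if (cnt == 0) NA_real_ else acc / cnt
    }, 0)
    out[, t] <- vals
  }
  out
}

#' Ca2+ fold increase of an intensity trace
#'
#' (mean of the last six frames - mean of the first six frames) divided
#' by the mean of the first six frames.
#'
#' @param trace per-frame intensity values, at least 12 frames.
#' @return unitless fold increase.
#' @export
calciumFoldIncrease <- function(trace) {
  n <- length(trace)
  if (n < 12L) stop("at least 12 frames are required")
  base <- mean(trace[1:6])
  if (base <= 0) stop("zero or negative baseline")
  (mean(trace[(n - 5):n]) - base) / base
}

#' Co-transfection mask by dual Otsu gating
#'
#' Logical AND of the per-channel Otsu foregrounds: pixels whose
#' intensity exceeds the Otsu threshold in both channels, selecting
#' cells that express both constructs.
#'
#' @param imgA,imgB numeric matrices of the two expression channels.
#' @return logical matrix.
#' @export
cotransfectionMask <- function(imgA, imgB) {
  if (!identical(dim(imgA), dim(imgB)))
    stop("images must share the same shape")
  (imgA > otsuThreshold(imgA)) & (imgB > otsuThreshold(imgB))
}

#' Expression-normalized staining intensity
#'
#' Mean staining intensity inside the mask, background-subtracted, per
#' unit of expression: \code{(mean(stain[mask]) - background) /
#' mean(expression[mask])}.  The background value is computed by the
#' caller from cells carrying only the expression construct (no
#' kinase), standardizing staining across sample groups.
#'
#' @param stainImg staining channel image.
#' @param expressionImg expression channel image.
#' @param mask logical matrix selecting co-expressing pixels.
#' @param background staining background intensity to subtract.
#' @return unitless normalized intensity.
#' @export
normalizedStaining <- function(stainImg, expressionImg, mask,
                               background = 0) {
  if (!any(mask)) stop("mask is empty")
  expr <- mean(expressionImg[mask])
  if (expr <= 0) stop("expression mean must be positive")
  (mean(stainImg[mask]) - background) / expr
}

#' Detect a single-cell footprint
#'
#' Sobel edge detection followed by clean-up: Otsu thresholding of the
#' gradient magnitude, dilation, interior hole filling, morphological
#' smoothing, and selection of the largest connected component.  Assumes
#' one cell per (pre-cropped) image.
#'
#' @param img numeric matrix.
#' @param minArea minimum footprint area in pixels.
#' @param brushSize diameter of the morphological structuring element.
#' @return logical footprint matrix.
#' @export
detectCell <- function(img, minArea = 50L, brushSize = 5L) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  sy <- t(sx)
  gx <- EBImage::filter2(img, sx)
  gy <- EBImage::filter2(img, sy)
  mag <- sqrt(gx^2 + gy^2)
  th <- tryCatch(otsuThreshold(mag),
                 error = function(e) stop("no edges detected"))
  edges <- mag > th
  if (!any(edges)) stop("no edges detected")
  brush <- EBImage::makeBrush(brushSize, "disc")
  m <- EBImage::dilate(edges, brush)
  m <- EBImage::fillHull(m)
  m <- EBImage::erode(m, brush)
  # the Sobel response band straddles the true boundary; erode by its
  # outer half-width so the footprint tracks the intensity edge
  m <- EBImage::erode(m, EBImage::makeBrush(3L, "disc"))
  m <- EBImage::opening(m, EBImage::makeBrush(3L, "disc"))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  if (max(lab) == 0) stop("no component above minimum area")
  areas <- tabulate(lab[lab > 0])
  if (max(areas) < minArea) stop("no component above minimum area")
  matrix(lab == which.max(areas), nrow(img), ncol(img))
}

#' Radial membrane/cytosol masks of a cell footprint
#'
#' Assigns each footprint pixel a normalized radial coordinate rising
#' from 0 at the centre of mass to 1 at the detected edge, implemented
#' as the distance-transform ratio \code{dC / (dC + dE)} with dC the
#' distance to the centre of mass and dE the distance to the footprint
#' edge.  The membrane mask is the outer shell whose normalized
#' edge-distance is at most \code{boundary} (i.e. radial coordinate >=
#' 1 - boundary); the cytosol is the remainder, so the two masks
#' partition the footprint exactly.  \code{convention = "inner"}
#' instead takes the literal 0-to-boundary radial interval as membrane.
#'
#' @param footprint logical matrix (connected, >= 10 pixels).
#' @param boundary shell boundary parameter in [0, 1] (default 0.25).
#' @param convention "outer" (membrane at the cell edge, default) or
#'   "inner" (raw interval convention).
#' @return A \linkS4class{RadialCellMask}.
#' @export
radialMasks <- function(footprint, boundary = 0.25,
                        convention = c("outer", "inner")) {
  convention <- match.arg(convention)
  footprint <- footprint > 0
  if (sum(footprint) < 10L) stop("degenerate footprint (< 10 pixels)")
  if (boundary < 0 || boundary > 1) stop("boundary must lie in [0, 1]")
  dE <- as.matrix(EBImage::distmap(footprint))
  cm <- c(mean(row(footprint)[footprint]), mean(col(footprint)[footprint]))
  dC <- sqrt((row(footprint) - cm[1])^2 + (col(footprint) - cm[2])^2)
  radial <- matrix(NA_real_, nrow(footprint), ncol(footprint))
  denom <- dC + dE
  inside <- footprint & denom > 0
  radial[inside] <- dC[inside] / denom[inside]
  radial[footprint & !inside] <- 0
  membrane <- footprint & if (convention == "outer")
    radial >= 1 - boundary else radial <= boundary
  membrane[is.na(membrane)] <- FALSE
  cytosol <- footprint & !membrane
  new("RadialCellMask", footprint = footprint, radial = radial,
      membrane = membrane, cytosol = cytosol, boundary = boundary)
}

#' Membrane translocation trace
#'
#' Per frame, the ratio of mean intensity in the membrane mask to mean
#' intensity in the cytosol mask, and its fold-change relative to the
#' mean ratio of the first four frames.
#'
#' @param stack a \linkS4class{TimeLapseStack} with at least 4 frames.
#' @param masks a \linkS4class{RadialCellMask}.
#' @param channel channel index or label.
#' @return A \linkS4class{TranslocationTrace}.
#' @export
translocationTrace <- function(stack, masks, channel = 1L) {
  d <- dim(stack@frames)
  if (d[1] < 4L) stop("at least 4 frames are required")
  if (!identical(dim(masks@footprint), d[2:3]))
    stop("mask shape must match the frames")
  ch <- .getChannel(stack, channel)
  ratio <- vapply(seq_len(d[1]), function(t) {
    fr <- ch[t, , ]
    cyt <- mean(fr[masks@cytosol])
    if (cyt <= 0) stop("zero cytosol mean; ratio undefined")
    mean(fr[masks@membrane]) / cyt
  }, 0)
  lab <- if (is.character(channel)) channel else
    stack@channelNames[channel]
  new("TranslocationTrace", ratio = ratio,
      foldChange = ratio / mean(ratio[1:4]), channel = lab)
}

#' Otsu-filtered Pearson colocalization coefficient
#'
#' Removes background by per-channel Otsu thresholding (retaining the
#' union of the two foregrounds) and computes the Pearson correlation
#' \deqn{\frac{\sum_i (G_i - \bar G)(R_i - \bar R)}
#'   {\sqrt{\sum_i (G_i - \bar G)^2 \sum_i (R_i - \bar R)^2}}}
#' over the retained pixels.
#'
#' @param imgA,imgB numeric matrices (the two channels).
#' @param combine "union" (default) or "intersection" of the
#'   per-channel foregrounds.
#' @return Pearson coefficient in [-1, 1].
#' @export
pearsonColocalization <- function(imgA, imgB,
                                  combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  if (!identical(dim(imgA), dim(imgB)))
    stop("images must share the same shape")
  fgA <- imgA > otsuThreshold(imgA)
  fgB <- imgB > otsuThreshold(imgB)
  keep <- if (combine == "union") fgA | fgB else fgA & fgB
  if (sum(keep) < 2L) stop("fewer than 2 retained pixels")
  a <- imgA[keep]; b <- imgB[keep]
  if (var(a) == 0 || var(b) == 0)
    stop("zero variance in a retained channel")
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}
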