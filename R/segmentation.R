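#' @include AllClasses.R
NULL

# 1-D Gaussian kernel, truncated at 3 sigma, normalized to unit sum.
.gaussKernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with reflected boundary.
.gaussBlur <- function(img, sigma) {
  k <- .gaussKernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  conv1 <- function(m) {                      # along rows
    n <- nrow(m)
    refl <- function(i) {                     # reflect indices into 1..n
      i <- abs(i - 1L) + 1L
      i <- ifelse(i > n, 2L * n - i, i)
      pmin(pmax(i, 1L), n)
    }
    mp <- m[refl(seq(1L - r, n + r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' Two-scale bandpass filter of a representative image
#'
#' Blurs the image with a Gaussian at the expected cell scale and at double
#' that scale; their difference is a bandpass of the original in which local
#' intensity variations at the cell scale are emphasized (a
#' difference-of-Gaussians filter). The blur sigmas are \code{kernel/2} and
#' \code{kernel} pixels, preserving the factor-2 scale ratio.
#'
#' @param image 2-D numeric matrix (typically
#'   \code{frameStatistic(movie, "representative")}).
#' @param kernelUm Cell length scale in micrometres (default 10, the
#'   characteristic islet-cell size). Used together with \code{pixelSizeUm};
#'   alternatively give \code{kernelPx} directly.
#' @param pixelSizeUm Pixel size in micrometres.
#' @param kernelPx Cell scale in pixels; overrides \code{kernelUm}.
#' @return Matrix of bandpass values, same shape as \code{image}.
#' @seealso [extractRois()]
#' @export
bandpassImage <- function(image, kernelUm = 10, pixelSizeUm = NULL,
                          kernelPx = NULL) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (is.null(kernelPx)) {
    if (is.null(pixelSizeUm))
      stop("give pixelSizeUm (to convert kernelUm) or kernelPx directly")
    kernelPx <- kernelUm / pixelSizeUm
  }
  if (kernelPx < 1) stop("kernel must be at least 1 px, got ", kernelPx)
  .gaussBlur(image, kernelPx / 2) - .gaussBlur(image, kernelPx)
}

#' Extract ROIs by local-peak pixel climbing
#'
#' Every pixel whose bandpass value exceeds \code{threshold} climbs by
#' steepest ascent over its 8-neighborhood until it reaches a local peak; all
#' pixels that lead to the same peak form one ROI. Ties on the ascent are
#' broken by (row, col) lexicographic order, making the labeling
#' deterministic. ROIs smaller than \code{minSize} pixels are discarded.
#' Labels are assigned in order of descending peak value.
#'
#' @param bp Bandpass image from [bandpassImage()].
#' @param threshold Minimum bandpass value for a pixel to take part
#'   (default 0: strictly positive pixels).
#' @param minSize Minimum ROI size in pixels (default 4).
#' @return A \linkS4class{ROISet}.
#' @export
extractRois <- function(bp, threshold = 0, minSize = 4L) {
  stopifnot(is.matrix(bp), all(is.finite(bp)))
  nr <- nrow(bp); nc <- ncol(bp)
  n <- nr * nc
  # steepest-ascent pointer for every pixel; 8-neighborhood, neighbors visited
  # in lexicographic (row, col) order so the first strict improvement wins ties
  best <- seq_len(n)
  bestVal <- as.numeric(bp)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2L:(nr + 1L), 2L:(nc + 1L)] <- bp
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  idxAll <- seq_len(n)
  row0 <- ((idxAll - 1L) %% nr) + 1L
  col0 <- ((idxAll - 1L) %/% nr) + 1L
  for (o in seq_len(nrow(offs))) {
    dr <- offs[o, 1L]; dc <- offs[o, 2L]
    nv <- as.numeric(pad[cbind(row0 + dr + 1L, col0 + dc + 1L)])
    better <- nv > bestVal
    if (any(better)) {
      tgt <- (col0[better] + dc - 1L) * nr + (row0[better] + dr)
      best[better] <- tgt
      bestVal[better] <- nv[better]
    }
  }
  # pointer jumping to the attracting peak
  root <- best
  repeat {
    nxt <- root[root]
    if (identical(nxt, root)) break
    root <- nxt
  }
  sup <- which(as.numeric(bp) > threshold)
  if (!length(sup)) {
    return(new("ROISet", labels = matrix(0L, nr, nc),
               peaks = data.frame(label = integer(), peak_row = integer(),
                                  peak_col = integer(), peak_value = numeric(),
                                  size_px = integer()),
               params = list(threshold = threshold, minSize = minSize)))
  }
  peakOf <- root[sup]
  tab <- table(peakOf)
  keepPeaks <- as.integer(names(tab)[tab >= minSize])
  # order peaks by descending bandpass value; deterministic tie-break on index
  pv <- as.numeric(bp)[keepPeaks]
  ord <- order(-pv, keepPeaks)
  keepPeaks <- keepPeaks[ord]
  lab <- matrix(0L, nr, nc)
  if (length(keepPeaks)) {
    m <- match(peakOf, keepPeaks)
    ok <- !is.na(m)
    lab[sup[ok]] <- m[ok]
  }
  peaks <- data.frame(
    label = seq_along(keepPeaks),
    peak_row = ((keepPeaks - 1L) %% nr) + 1L,
    peak_col = ((keepPeaks - 1L) %/% nr) + 1L,
    peak_value = as.numeric(bp)[keepPeaks],
    size_px = as.integer(tab[as.character(keepPeaks)])
  )
  new("ROISet", labels = lab, peaks = peaks,
      params = list(threshold = threshold, minSize = as.integer(minSize)))
}

#' Segment a movie into ROIs
#'
#' Convenience wrapper: representative frame statistic, bandpass at the cell
#' scale, local-peak climbing.
#'
#' @param movie A \linkS4class{CaMovie}.
#' @param kernelUm Cell scale in micrometres.
#' @param statistic Frame statistic kind passed to [frameStatistic()].
#' @param threshold,minSize Passed to [extractRois()].
#' @param robustRank Passed to [frameStatistic()].
#' @return A \linkS4class{ROISet}.
#' @export
segmentMovie <- function(movie, kernelUm = 10, statistic = "representative",
                         threshold = 0, minSize = 4L, robustRank = 10L) {
  img <- frameStatistic(movie, statistic, robustRank = robustRank)
  bp <- bandpassImage(img, kernelUm = kernelUm, pixelSizeUm = pixelSize(movie))
  extractRois(bp, threshold = threshold, minSize = minSize)
}

#' Write the ROI table as CSV and the label image as 16-bit TIFF
#'
#' @param rois A \linkS4class{ROISet}.
#' @param csvPath Path for the ROI table (label, peak_row, peak_col, size_px).
#' @param tiffPath Optional path for the label image.
#' @export
writeRoiTable <- function(rois, csvPath, tiffPath = NULL) {
  stopifnot(is(rois, "ROISet"))
  utils::write.csv(roiTable(rois), csvPath, row.names = FALSE)
  if (!is.null(tiffPath))
    tiff::writeTIFF(labelMatrix(rois) / 65535, tiffPath, bits.per.sample = 16L)
  invisible(csvPath)
}
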