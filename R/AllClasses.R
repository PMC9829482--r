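#' @include AllGenerics.R
NULL

#' CaMovie: a photon-counting fluorescence movie
#'
#' Container for a time-lapse fluorescence recording stored as a 3-D array
#' indexed \code{(frame, row, col)}, together with the acquisition metadata the
#' pipeline needs: frame rate (Hz), pixel size (um) and the detector gain (the
#' slope of the per-pixel variance-vs-mean line; 1 for an ideal photon counter,
#' where values are Poisson-distributed with variance equal to the mean).
#'
#' @slot data Numeric 3-D array \code{(frame, row, col)} of non-negative values.
#' @slot frameRate Acquisition rate in Hz (positive).
#' @slot pixelSize Pixel side length in micrometres (positive).
#' @slot gain Detector variance/mean slope (positive, default 1).
#'
#' @seealso [CaMovie()], [loadMovie()], [frameStatistic()], [estimateMotion()]
#' @export
setClass("CaMovie",
  representation(
    data = "array",
    frameRate = "numeric",
    pixelSize = "numeric",
    gain = "numeric"
  )
)

setValidity("CaMovie", function(object) {
  d <- object@data
  msg <- character()
  if (length(dim(d)) != 3L)
    msg <- c(msg, "data must be a 3-D array (frame, row, col)")
  else {
    if (dim(d)[1L] < 1L) msg <- c(msg, "movie must contain at least one frame")
    if (anyNA(d) || any(!is.finite(d))) msg <- c(msg, "data must be finite")
    else if (any(d < 0)) msg <- c(msg, "data must be non-negative")
  }
  for (s in c("frameRate", "pixelSize", "gain")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single finite positive number", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CaMovie
#'
#' @param data 3-D numeric array \code{(frame, row, col)} of non-negative
#'   intensities (photon counts for an ideal detector).
#' @param frameRate Frame rate in Hz.
#' @param pixelSize Pixel size in micrometres.
#' @param gain Detector variance/mean slope; 1 for photon counting.
#' @return A \linkS4class{CaMovie}.
#' @examples
#' mov <- CaMovie(array(rpois(4 * 8 * 8, 5), c(4, 8, 8)), frameRate = 20, pixelSize = 1)
#' nFrames(mov)
#' @export
CaMovie <- function(data, frameRate, pixelSize, gain = 1) {
  new("CaMovie", data = data, frameRate = as.numeric(frameRate),
      pixelSize = as.numeric(pixelSize), gain = as.numeric(gain))
}

#' @rdname accessors
#' @export
setMethod("movieData", "CaMovie", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("frameRate", "CaMovie", function(x) x@frameRate)

#' @rdname accessors
#' @export
setMethod("pixelSize", "CaMovie", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("detectorGain", "CaMovie", function(x) x@gain)

#' @rdname accessors
#' @export
setReplaceMethod("detectorGain", "CaMovie", function(x, value) {
  x@gain <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("nFrames", "CaMovie", function(x) dim(x@data)[1L])

#' @describeIn CaMovie Spatial and temporal dimensions \code{(frame, row, col)}.
#' @param x A \code{CaMovie}.
#' @export
setMethod("dim", "CaMovie", function(x) dim(x@data))

setMethod("show", "CaMovie", function(object) {
  d <- dim(object@data)
  cat(sprintf("CaMovie: %d frames of %d x %d px\n", d[1L], d[2L], d[3L]))
  cat(sprintf("  frame rate: %g Hz (%.1f s), pixel size: %g um, gain: %g\n",
              object@frameRate, d[1L] / object@frameRate,
              object@pixelSize, object@gain))
})

#' ROISet: segmented regions of interest
#'
#' The result of bandpass segmentation: a label image in which every
#' suprathreshold pixel carries the id of the ROI it climbed to (0 =
#' background), plus a per-ROI table with the local-peak coordinates, the peak
#' bandpass value and the pixel count. Labels are ordered by descending peak
#' value.
#'
#' @slot labels Integer matrix, same spatial shape as the source image; 0 marks
#'   background.
#' @slot peaks \code{data.frame} with columns \code{label}, \code{peak_row},
#'   \code{peak_col}, \code{peak_value}, \code{size_px}.
#' @slot params List of the segmentation parameters used.
#' @seealso [extractRois()], [bandpassImage()]
#' @export
setClass("ROISet",
  representation(labels = "matrix", peaks = "data.frame", params = "list")
)

setValidity("ROISet", function(object) {
  msg <- character()
  p <- object@peaks
  need <- c("label", "peak_row", "peak_col", "peak_value", "size_px")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("peaks must have columns", paste(need, collapse = ", ")))
  else if (nrow(p)) {
    if (anyDuplicated(p$label)) msg <- c(msg, "labels must be unique")
    lab <- object@labels
    idx <- cbind(p$peak_row, p$peak_col)
    if (any(p$peak_row < 1 | p$peak_row > nrow(lab) |
            p$peak_col < 1 | p$peak_col > ncol(lab)))
      msg <- c(msg, "peak coordinates out of bounds")
    else if (any(lab[idx] != p$label))
      msg <- c(msg, "each peak must lie inside its own ROI")
    if (!isTRUE(all.equal(sort(as.integer(p$label)),
                          sort(unique(as.integer(lab[lab > 0L]))))))
      msg <- c(msg, "label matrix and peak table disagree")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("labelMatrix", "ROISet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("roiTable", "ROISet", function(x) x@peaks)

#' @rdname accessors
#' @export
setMethod("nRois", "ROISet", function(x) nrow(x@peaks))

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d ROIs on a %d x %d px field\n",
              nrow(object@peaks), nrow(object@labels), ncol(object@labels)))
  if (nrow(object@peaks)) {
    cat(sprintf("  sizes %d-%d px; top peak value %.3g\n",
                min(object@peaks$size_px), max(object@peaks$size_px),
                max(object@peaks$peak_value)))
  }
})

#' Pixel coordinates of one ROI
#'
#' @param rois A \linkS4class{ROISet}.
#' @param label ROI id.
#' @return Two-column integer matrix \code{(row, col)}.
#' @export
roiPixels <- function(rois, label) {
  stopifnot(is(rois, "ROISet"))
  w <- which(rois@labels == label, arr.ind = TRUE)
  if (!nrow(w)) stop("no ROI with label ", label)
  colnames(w) <- c("row", "col")
  w
}

#' ZScoredTrace: a trace with its slow component and Poisson z-score
#'
#' Holds a summed ROI (or pixel) time series \code{x}, the slow component
#' \code{mu} estimated by iterative zero-phase low-pass filtering, and the
#' z-score \code{z = (x - mu) / sqrt(gain * mu)}, which recasts deviations from
#' the slow baseline in units of the Poisson standard deviation.
#'
#' @slot x Numeric trace (sum over ROI pixels per frame).
#' @slot mu Slow component, same length as \code{x}.
#' @slot z z-score, same length as \code{x}.
#' @slot frameRate Sampling rate in Hz.
#' @slot fCut Low-pass cutoff frequency in Hz used for \code{mu}.
#' @slot nIter Number of outlier-replacement iterations applied.
#' @slot gain Detector variance/mean slope used in the denominator.
#' @slot flagged Integer indices where \code{mu} fell below the guard value and
#'   \code{z} was set to 0.
#' @seealso [zscoreTrace()], [detectCandidates()]
#' @export
setClass("ZScoredTrace",
  representation(
    x = "numeric", mu = "numeric", z = "numeric",
    frameRate = "numeric", fCut = "numeric", nIter = "integer",
    gain = "numeric", flagged = "integer"
  )
)

setValidity("ZScoredTrace", function(object) {
  msg <- character()
  n <- length(object@x)
  if (length(object@mu) != n || length(object@z) != n)
    msg <- c(msg, "x, mu and z must have equal length")
  if (object@fCut >= object@frameRate / 2)
    msg <- c(msg, "fCut must be below the Nyquist frequency")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ZScoredTrace", function(object) {
  cat(sprintf(
    "ZScoredTrace: %d samples at %g Hz; f_cut = %g Hz (tau = %.3g s), %d iterations\n",
    length(object@x), object@frameRate, object@fCut, 1 / object@fCut,
    object@nIter))
  cat(sprintf("  max z = %.2f; %d guarded low-mu samples\n",
              max(object@z), length(object@flagged)))
})

#' @describeIn ZScoredTrace Number of samples.
#' @param x A \code{ZScoredTrace}.
#' @export
setMethod("length", "ZScoredTrace", function(x) length(x@x))
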