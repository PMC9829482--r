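#' @include AllGenerics.R
NULL

#' Accessors for CaMovie objects
#'
#' @param x A \linkS4class{CaMovie} or \linkS4class{ROISet} object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("detectorGain", function(x) standardGeneric("detectorGain"))

#' @rdname accessors
#' @param value Replacement value.
#' @export
setGeneric("detectorGain<-", function(x, value) standardGeneric("detectorGain<-"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))

#' @rdname accessors
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))

#' Per-pixel statistic images over the frames of a movie
#'
#' @param movie A \linkS4class{CaMovie}.
#' @param ... Further arguments passed to methods.
#' @export
setGeneric("frameStatistic", function(movie, ...) standardGeneric("frameStatistic"))

#' Temporal rebinning of movies and traces
#'
#' @param x A \linkS4class{CaMovie} or a numeric trace.
#' @param factor Integer rebinning factor (consecutive groups of \code{factor}
#'   frames are combined; trailing frames that do not fill a group are dropped).
#' @param mode \code{"sum"} (preserves the Poisson count interpretation) or
#'   \code{"mean"}.
#' @export
setGeneric("rebinTime", function(x, factor, mode = c("sum", "mean"))
  standardGeneric("rebinTime"))

#' Rigid motion estimation and correction
#'
#' @param movie A \linkS4class{CaMovie}.
#' @param ... Further arguments passed to methods.
#' @export
setGeneric("estimateMotion", function(movie, ...) standardGeneric("estimateMotion"))

#' @rdname estimateMotion
#' @param offsets A data frame of per-frame \code{(dy, dx)} offsets as returned
#'   by \code{estimateMotion}.
#' @export
setGeneric("applyMotion", function(movie, offsets) standardGeneric("applyMotion"))

#' Extract summed traces for regions of interest
#'
#' @param movie A \linkS4class{CaMovie}.
#' @param rois A \linkS4class{ROISet}.
#' @param ... Further arguments passed to methods.
#' @export
setGeneric("roiTrace", function(movie, rois, ...) standardGeneric("roiTrace"))

#' @rdname roiTrace
#' @export
setGeneric("roiTraces", function(movie, rois, ...) standardGeneric("roiTraces"))
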