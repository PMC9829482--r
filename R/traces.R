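#' @include AllClasses.R
NULL

#' @describeIn roiTrace Summed trace of one ROI.
#'
#' The sum (never the average) over member pixels is used: a sum of
#' independent Poisson pixels is again Poisson, so its standard deviation is
#' the square root of its mean and the z-score keeps its calibration. The
#' average would shrink deviations by the pixel count's square root.
#'
#' @param label ROI id.
#' @return Numeric vector, one value per frame.
#' @export
setMethod("roiTrace", c("CaMovie", "ROISet"), function(movie, rois, label) {
  px <- roiPixels(rois, label)
  d <- movieData(movie)
  if (any(px[, 1L] > dim(d)[2L]) || any(px[, 2L] > dim(d)[3L]))
    stop("ROI pixels outside movie bounds")
  flat <- matrix(d, nrow = dim(d)[1L])
  lin <- (px[, 2L] - 1L) * dim(d)[2L] + px[, 1L]
  rowSums(flat[, lin, drop = FALSE])
})

#' @describeIn roiTrace Matrix of summed traces, one column per ROI
#'   (column names are the labels).
#' @export
setMethod("roiTraces", c("CaMovie", "ROISet"), function(movie, rois) {
  labs <- roiTable(rois)$label
  out <- vapply(labs, function(l) roiTrace(movie, rois, l),
                numeric(nFrames(movie)))
  colnames(out) <- labs
  out
})

#' Slow component and Poisson z-score of a trace
#'
#' Estimates the slow component \eqn{\mu} of a count trace by zero-phase
#' second-order-section Butterworth low-pass filtering, then transforms the
#' trace to the standard score \eqn{z = (x - \mu)/\sqrt{g\mu}}, the deviation
#' from the slow baseline in units of the Poisson standard deviation (with
#' detector gain \eqn{g}).
#'
#' Because a plain low-pass is distorted by the events themselves (the
#' baseline is dragged upwards), the estimate is refined iteratively: at each
#' iteration, samples whose current z exceeds \code{zOut} are replaced by the
#' current slow component and the filter is reapplied. Each iteration reduces
#' the leakage of events into \eqn{\mu} and increases the z-score of true
#' events. Three iterations are the default, a conservative compromise
#' between accuracy and computing time.
#'
#' @param x Numeric count trace (a summed ROI trace).
#' @param frameRate Sampling rate in Hz.
#' @param fCut Low-pass cutoff in Hz; the timescale of events detectable in
#'   z is \code{tau = 1/fCut}. Must be below the Nyquist frequency.
#' @param nIter Number of outlier-replacement iterations (default 3;
#'   0 gives the plain low-pass).
#' @param zOut Replacement threshold during iteration (default 3, one-sided:
#'   only positive-going outliers are replaced, since events are
#'   positive-going).
#' @param gain Detector variance/mean slope (default 1).
#' @param zeroPhase Forward-backward filtering (default TRUE; FALSE gives a
#'   causal single pass with phase lag).
#' @param muGuard Samples where \eqn{\mu \le} \code{muGuard} (default 1 count)
#'   get z = 0 and are flagged, avoiding division blow-up on dark pixels.
#' @return A \linkS4class{ZScoredTrace}.
#' @seealso [detectCandidates()], [multiscaleScan()]
#' @export
zscoreTrace <- function(x, frameRate, fCut, nIter = 3L, zOut = 3,
                        gain = 1, zeroPhase = TRUE, muGuard = 1) {
  stopifnot(is.numeric(x), length(x) >= 8L)
  .assertScalar(frameRate, "frameRate")
  .assertScalar(fCut, "fCut")
  if (fCut >= frameRate / 2)
    stop("fCut (", fCut, " Hz) must be below the Nyquist frequency (",
         frameRate / 2, " Hz)")
  nIter <- as.integer(nIter)
  if (nIter < 0L) stop("nIter must be >= 0")

  zOf <- function(mu) {
    den <- sqrt(gain * pmax(mu, muGuard))
    z <- (x - mu) / den
    z[mu <= muGuard] <- 0
    z
  }
  mu <- .lowpass(x, fCut, frameRate, zeroPhase)
  if (nIter > 0L) {
    for (k in seq_len(nIter)) {
      z <- zOf(mu)
      xr <- x
      out <- z > zOut
      xr[out] <- mu[out]
      mu <- .lowpass(xr, fCut, frameRate, zeroPhase)
    }
  }
  z <- zOf(mu)
  new("ZScoredTrace", x = as.numeric(x), mu = mu, z = z,
      frameRate = frameRate, fCut = fCut, nIter = nIter, gain = gain,
      flagged = which(mu <= muGuard))
}

#' @rdname zscoreTrace
#' @param zs A \linkS4class{ZScoredTrace}.
#' @export
slowComponent <- function(zs) { stopifnot(is(zs, "ZScoredTrace")); zs@mu }

#' @rdname zscoreTrace
#' @export
zScore <- function(zs) { stopifnot(is(zs, "ZScoredTrace")); zs@z }

#' @rdname zscoreTrace
#' @export
traceValues <- function(zs) { stopifnot(is(zs, "ZScoredTrace")); zs@x }

#' Calibrate the detector gain from a quasi-stationary movie
#'
#' For photon-counting detectors the per-pixel temporal variance equals the
#' mean (Poisson); other detectors keep the linear variance-vs-mean relation
#' but with a different slope. The slope is estimated robustly as the median
#' of per-pixel variance/mean ratios (a line through the origin), and is used
#' as the \code{gain} in z-scoring.
#'
#' @param movie A \linkS4class{CaMovie} with at least 100 frames of
#'   quasi-stationary signal.
#' @return The gain (scalar).
#' @export
calibrateGain <- function(movie) {
  stopifnot(is(movie, "CaMovie"))
  d <- movieData(movie)
  nT <- dim(d)[1L]
  if (nT < 100L)
    stop("gain calibration needs >= 100 quasi-stationary frames, got ", nT)
  flat <- matrix(d, nrow = nT)
  mu <- colMeans(flat)
  v <- (colSums(flat^2) - nT * mu^2) / (nT - 1)
  ok <- mu > 0 & is.finite(v)
  if (!any(ok) || all(v[ok] == 0))
    stop("gain calibration impossible: movie has no temporal variance")
  stats::median(v[ok] / mu[ok])
}
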