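#' @include AllClasses.R
NULL

#' Read a movie from a multipage TIFF stack
#'
#' Pages are taken in acquisition order as frames. Pixel values are read
#' natively (integer counts for 8/16-bit stacks, reals for float stacks).
#'
#' @param path Path to a multipage TIFF file.
#' @param frameRate Frame rate in Hz.
#' @param pixelSize Pixel size in micrometres.
#' @param gain Detector variance/mean slope (default 1, photon counting).
#' @return A \linkS4class{CaMovie}.
#' @seealso [writeMovie()], [frameStatistic()]
#' @export
loadMovie <- function(path, frameRate, pixelSize, gain = 1) {
  if (!file.exists(path)) stop("cannot read movie file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("expected a multipage (3-D) stack, got ", length(pages), " page(s)")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all pages must share the same shape")
  arr <- array(0, c(length(pages), dims[1, 1], dims[2, 1]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  CaMovie(arr, frameRate = frameRate, pixelSize = pixelSize, gain = gain)
}

#' Write a movie as a 16-bit multipage TIFF
#'
#' Counts are stored natively as 16-bit integers; values above 65535 are
#' clipped with a warning.
#'
#' @param movie A \linkS4class{CaMovie}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "CaMovie"))
  d <- movieData(movie)
  if (max(d) > 65535) {
    warning("values above 65535 clipped for 16-bit TIFF output")
    d[d > 65535] <- 65535
  }
  pages <- lapply(seq_len(dim(d)[1L]), function(i) round(d[i, , ]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @describeIn frameStatistic Per-pixel statistic over frames.
#'
#' Supported kinds: \code{mean} and \code{std} over frames; \code{diff_mean}
#' and \code{diff_std} on the first temporal difference (sensitive to fast
#' activity); \code{robust_max}, the \code{robustRank}-th largest absolute
#' value of each pixel's time series (an outlier-resistant maximum, sensitive
#' to cells that fire rarely so that their mean is negligible); and
#' \code{representative}, the arithmetic mean of the mean image and the
#' robust-maximum image, the default input for segmentation.
#'
#' @param kind One of \code{"mean"}, \code{"std"}, \code{"diff_mean"},
#'   \code{"diff_std"}, \code{"robust_max"}, \code{"representative"}.
#' @param robustRank Order statistic for \code{robust_max}: the k-th largest
#'   absolute value per pixel (default 10).
#' @return A 2-D matrix matching the movie's spatial shape.
#' @export
setMethod("frameStatistic", "CaMovie", function(movie,
    kind = c("representative", "mean", "std", "diff_mean", "diff_std",
             "robust_max"),
    robustRank = 10L) {
  kind <- match.arg(kind)
  d <- movieData(movie)
  nT <- dim(d)[1L]
  flat <- matrix(d, nrow = nT)                # frames x pixels

  pixStat <- function(m, f) matrix(f(m), dim(d)[2L], dim(d)[3L])
  colSd <- function(m) {
    n <- nrow(m)
    if (n < 2L) return(rep(0, ncol(m)))
    mu <- colMeans(m)
    sqrt(pmax(0, (colSums(m^2) - n * mu^2) / (n - 1)))
  }
  robustMax <- function(m, k) {
    if (nrow(m) < k)
      stop("robust_max needs at least robustRank = ", k, " frames, got ", nrow(m))
    a <- abs(m)
    apply(a, 2L, function(v) -sort(-v, partial = k)[k])
  }

  img <- switch(kind,
    mean = pixStat(flat, colMeans),
    std = pixStat(flat, colSd),
    diff_mean = {
      if (nT < 2L) stop("diff statistics need at least 2 frames")
      pixStat(flat[-1L, , drop = FALSE] - flat[-nT, , drop = FALSE], colMeans)
    },
    diff_std = {
      if (nT < 2L) stop("diff statistics need at least 2 frames")
      pixStat(flat[-1L, , drop = FALSE] - flat[-nT, , drop = FALSE], colSd)
    },
    robust_max = pixStat(flat, function(m) robustMax(m, as.integer(robustRank))),
    representative = {
      (pixStat(flat, colMeans) +
       pixStat(flat, function(m) robustMax(m, as.integer(robustRank)))) / 2
    })
  img
})

#' @describeIn rebinTime Rebin a movie in time. The frame rate is divided by
#'   \code{factor}; \code{sum} mode preserves the Poisson count interpretation
#'   of the data (the variance of a rebinned count trace stays equal to
#'   gain times its mean).
#' @export
setMethod("rebinTime", "CaMovie", function(x, factor, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  n <- as.integer(factor)
  if (is.na(n) || n < 1L) stop("rebin factor must be an integer >= 1")
  if (n == 1L) return(x)
  d <- movieData(x)
  nT <- dim(d)[1L]
  nG <- nT %/% n
  if (nG < 1L) stop("rebin factor ", n, " exceeds the number of frames ", nT)
  drop <- nT - nG * n
  if (drop > 0L)
    message("rebinTime: dropping ", drop, " trailing frame(s)")
  flat <- matrix(d[seq_len(nG * n), , ], nrow = nG * n)
  g <- array(flat, c(n, nG, ncol(flat)))
  out <- colSums(g)                            # nG x pixels
  if (mode == "mean") out <- out / n
  CaMovie(array(out, c(nG, dim(d)[2L], dim(d)[3L])),
          frameRate = frameRate(x) / n, pixelSize = pixelSize(x),
          gain = detectorGain(x))
})

#' @describeIn rebinTime Rebin a numeric trace.
#' @export
setMethod("rebinTime", "numeric", function(x, factor, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  n <- as.integer(factor)
  if (is.na(n) || n < 1L) stop("rebin factor must be an integer >= 1")
  if (n == 1L) return(x)
  nG <- length(x) %/% n
  if (nG < 1L) stop("rebin factor exceeds trace length")
  drop <- length(x) - nG * n
  if (drop > 0L) message("rebinTime: dropping ", drop, " trailing sample(s)")
  out <- colSums(matrix(x[seq_len(nG * n)], nrow = n))
  if (mode == "mean") out / n else out
})

#' @describeIn estimateMotion Estimate rigid per-frame translation offsets.
#'
#' The movie is rebinned to a moderate working rate (a few Hz) to suppress
#' shot noise, each rebinned frame is aligned to a template (the mean of the
#' rebinned movie) by maximizing the translation cross-correlation (computed
#' via FFT), and the offsets are broadcast back to every original frame.
#' Offsets follow the correction convention: applying them with
#' \code{\link{applyMotion}} undoes the drift.
#'
#' @param workRate Working rate in Hz for the rebinned estimation pass.
#' @param maxShift Largest |offset| considered, in pixels.
#' @return \code{data.frame(frame, dy, dx)} with one row per original frame.
#' @export
setMethod("estimateMotion", "CaMovie", function(movie, workRate = 2,
                                                maxShift = 16L) {
  .assertScalar(workRate, "workRate")
  if (nFrames(movie) < 2L) stop("motion estimation needs at least 2 frames")
  fac <- max(1L, as.integer(round(frameRate(movie) / workRate)))
  reb <- suppressMessages(rebinTime(movie, fac, mode = "mean"))
  d <- movieData(reb)
  nT <- dim(d)[1L]; nr <- dim(d)[2L]; nc <- dim(d)[3L]
  maxShift <- min(as.integer(maxShift), nr %/% 2 - 1L, nc %/% 2 - 1L)
  template <- colMeans(matrix(d, nrow = nT))
  template <- matrix(template, nr, nc)
  t0 <- template - mean(template)
  if (sd(t0) < .Machine$double.eps^0.5) {
    warning("flat movie: motion offsets set to zero")
    return(data.frame(frame = seq_len(nFrames(movie)), dy = 0L, dx = 0L))
  }
  Ft <- stats::fft(t0)
  keep <- function(k, n) c(0:maxShift, (n - maxShift):(n - 1L))
  rows <- keep(maxShift, nr) + 1L
  cols <- keep(maxShift, nc) + 1L
  toShift <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)

  off <- matrix(0L, nT, 2L)
  for (i in seq_len(nT)) {
    f0 <- d[i, , ] - mean(d[i, , ])
    cc <- Re(stats::fft(Ft * Conj(stats::fft(f0)), inverse = TRUE))
    sub <- cc[rows, cols]
    best <- which(sub == max(sub), arr.ind = TRUE)
    dy <- toShift(rows[best[, 1L]], nr)
    dx <- toShift(cols[best[, 2L]], nc)
    # deterministic tie-break: smallest displacement first
    ord <- order(abs(dy) + abs(dx), dy, dx)
    off[i, ] <- c(dy[ord[1L]], dx[ord[1L]])
  }
  idx <- pmin(((seq_len(nFrames(movie)) - 1L) %/% fac) + 1L, nT)
  data.frame(frame = seq_len(nFrames(movie)),
             dy = off[idx, 1L], dx = off[idx, 2L])
})

#' @describeIn estimateMotion Apply per-frame translation offsets. Each frame
#'   is shifted by its (integer-rounded) \code{(dy, dx)}; pixels shifted in
#'   from outside the field are filled with 0 (neutral for count data).
#' @export
setMethod("applyMotion", "CaMovie", function(movie, offsets) {
  stopifnot(is.data.frame(offsets), all(c("dy", "dx") %in% names(offsets)))
  d <- movieData(movie)
  if (nrow(offsets) != dim(d)[1L])
    stop("offsets must have one row per frame (", dim(d)[1L], "), got ",
         nrow(offsets))
  out <- d
  dy <- as.integer(round(offsets$dy))
  dx <- as.integer(round(offsets$dx))
  for (i in seq_len(dim(d)[1L])) {
    if (dy[i] != 0L || dx[i] != 0L)
      out[i, , ] <- .shiftMatrix(d[i, , ], dy[i], dx[i])
  }
  CaMovie(out, frameRate = frameRate(movie), pixelSize = pixelSize(movie),
          gain = detectorGain(movie))
})

#' Write motion offsets as CSV
#'
#' @param offsets Data frame from [estimateMotion()].
#' @param path Output CSV path.
#' @export
writeOffsets <- function(offsets, path) {
  utils::write.csv(offsets, path, row.names = FALSE)
  invisible(path)
}
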