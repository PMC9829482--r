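#' @include AllClasses.R
NULL

#' Geometric ladder of detection timescales
#'
#' Timescales start at 0.5 s and increase by a factor of \eqn{2^{1/4}} up to
#' \code{tauMax}, so that four consecutive rungs span a factor of two. An
#' event detectable at timescales differing at least twofold therefore shows
#' up on at least four rungs.
#'
#' @param tauMax Longest timescale of interest in seconds (default 128).
#' @param tauMin First rung in seconds (default 0.5).
#' @return Numeric vector of timescales (seconds), ascending.
#' @export
timescaleLadder <- function(tauMax = 128, tauMin = 0.5) {
  .assertScalar(tauMax, "tauMax"); .assertScalar(tauMin, "tauMin")
  if (tauMax < tauMin) stop("tauMax must be >= tauMin")
  k <- 0:floor(log2(tauMax / tauMin) * 4 + 1e-9)
  tauMin * 2^(k / 4)
}

# Interpolated half-maximum crossings of d around the peak at ipk.
# Returns c(t0, tEnd, halfwidth) with sample i at time (i-1)/fs.
.halfCrossings <- function(d, ipk, fs) {
  n <- length(d)
  h <- d[ipk]
  half <- h / 2
  j <- ipk
  while (j > 1L && d[j - 1L] >= half) j <- j - 1L
  t0 <- if (j == 1L) 0 else
    (j - 2L + (half - d[j - 1L]) / (d[j] - d[j - 1L])) / fs
  j <- ipk
  while (j < n && d[j + 1L] >= half) j <- j + 1L
  tEnd <- if (j == n) (n - 1L) / fs else
    (j - 1L + (d[j] - half) / (d[j] - d[j + 1L])) / fs
  c(t0, tEnd, tEnd - t0)
}

#' Detect candidate events in a z-scored trace
#'
#' Each maximal contiguous region with \code{z > zThresh} yields one
#' candidate (z is the per-frame Poisson z-score: a single frame of 150
#' counts on a slow component of 100 has z = 5 and contributes).
#'
#' Height and halfwidth are then measured on the background-subtracted trace
#' \eqn{d = \tilde{x} - \mu}, where \eqn{\tilde{x}} is the trace low-passed
#' at a cutoff adapted to the event's own width (4 / width, capped at 0.3
#' times the sampling rate), so that measurement noise scales with the event
#' rather than with the sampling rate. The width estimate starts from the
#' suprathreshold region length and is refined twice. The half-maximum
#' crossings of \eqn{d} around the peak, located by linear interpolation
#' while walking outwards, give the start time \eqn{t_0} and end time
#' \eqn{t_{end}}; the halfwidth is \eqn{\delta t = t_{end} - t_0}. Sample
#' \code{i} is at time \code{(i-1)/frameRate} seconds.
#'
#' @param zs A \linkS4class{ZScoredTrace} (computed with \code{fCut = 1/tau}
#'   for detection at timescale \code{tau}).
#' @param zThresh Detection threshold (default 4).
#' @return \code{data.frame(t0_s, t_end_s, halfwidth_s, height, z_max)}; empty
#'   if nothing crosses the threshold.
#' @seealso [multiscaleScan()], [distillEvents()]
#' @export
detectCandidates <- function(zs, zThresh = 4) {
  stopifnot(is(zs, "ZScoredTrace"))
  z <- zs@z
  x <- zs@x
  mu <- zs@mu
  fs <- zs@frameRate
  above <- z > zThresh
  empty <- data.frame(t0_s = numeric(), t_end_s = numeric(),
                      halfwidth_s = numeric(), height = numeric(),
                      z_max = numeric())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  fmMax <- 0.3 * fs
  measure <- function(i1, i2) {
    # adaptive half-maximum measurement seeded by the region length
    hw <- max((i2 - i1 + 1L) / fs, 2 / fs)
    cr <- NULL; h <- NA_real_
    for (iter in 1:3) {
      fm <- min(fmMax, 4 / hw)
      ds <- .lowpass(x, fm, fs) - mu
      ipk <- i1 - 1L + which.max(ds[i1:i2])
      h <- ds[ipk]
      if (h <= 0) return(NULL)
      cr <- .halfCrossings(ds, ipk, fs)
      if (cr[3L] <= 0) return(NULL)
      if (abs(cr[3L] - hw) < 0.5 / fs) { hw <- cr[3L]; break }
      hw <- cr[3L]
    }
    data.frame(t0_s = cr[1L], t_end_s = cr[2L], halfwidth_s = cr[3L],
               height = h, z_max = max(z[i1:i2]))
  }
  rows <- lapply(seq_along(starts), function(k) measure(starts[k], ends[k]))
  ok <- !vapply(rows, is.null, logical(1))
  rows <- rows[ok]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # The suprathreshold region of one event can fragment at its flanks (or,
  # for long events, during the iterative unmasking) where z hovers near the
  # threshold; the fragments' measured intervals then coincide. They are one
  # detection: re-measure each group of overlapping intervals over the union
  # of its regions, so the walk starts from the true event peak with the
  # union-scaled smoothing. This leaves one candidate per event per
  # timescale -- the unit the distilling scale-count rules are written in.
  ord <- order(out$t0_s)
  out <- out[ord, , drop = FALSE]
  reg <- cbind(starts[ok], ends[ok])[ord, , drop = FALSE]
  n <- nrow(out)
  grp <- integer(n)
  g <- 1L
  grp[1L] <- 1L
  if (n > 1L) {
    end <- out$t_end_s[1L]
    for (i in 2:n) {
      if (out$t0_s[i] < end) end <- max(end, out$t_end_s[i])
      else { g <- g + 1L; end <- out$t_end_s[i] }
      grp[i] <- g
    }
  }
  merged <- lapply(split(seq_len(n), grp), function(ix) {
    if (length(ix) == 1L) return(out[ix, , drop = FALSE])
    m <- measure(min(reg[ix, 1L]), max(reg[ix, 2L]))
    if (is.null(m)) return(NULL)
    m$z_max <- max(out$z_max[ix])
    m
  })
  merged <- merged[!vapply(merged, is.null, logical(1))]
  if (!length(merged)) return(empty)
  out <- do.call(rbind, merged)
  out <- out[order(out$t0_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a trace for candidate events over a ladder of timescales
#'
#' Sequentially z-scores the trace with \code{fCut = 1/tau} for every rung of
#' the ladder and collects the candidates from each, tagged with their
#' detection timescale. This is the first step of the two-step detection; the
#' second is [distillEvents()].
#'
#' @param x Numeric count trace.
#' @param frameRate Sampling rate in Hz.
#' @param ladder Timescales in seconds from [timescaleLadder()]; the largest
#'   must be shorter than the recording.
#' @param zThresh Detection threshold (default 4).
#' @param nIter,zOut,gain,zeroPhase Passed to [zscoreTrace()].
#' @return \code{data.frame(tau_s, t0_s, t_end_s, halfwidth_s, height, z_max)}.
#' @export
multiscaleScan <- function(x, frameRate, ladder = timescaleLadder(),
                           zThresh = 4, nIter = 3L, zOut = 3, gain = 1,
                           zeroPhase = TRUE) {
  duration <- length(x) / frameRate
  if (max(ladder) >= duration)
    stop("largest timescale (", max(ladder),
         " s) must be shorter than the recording (", duration, " s)")
  res <- lapply(ladder, function(tau) {
    zs <- zscoreTrace(x, frameRate, fCut = 1 / tau, nIter = nIter,
                      zOut = zOut, gain = gain, zeroPhase = zeroPhase)
    cand <- detectCandidates(zs, zThresh = zThresh)
    if (nrow(cand)) cbind(tau_s = tau, cand) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(tau_s = numeric(), t0_s = numeric(),
                      t_end_s = numeric(), halfwidth_s = numeric(),
                      height = numeric(), z_max = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Single-linkage clustering of candidates under the cognate test.
.cognateComponents <- function(t0, tEnd, hw, tol) {
  n <- length(t0)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m <- tol * max(hw[i], hw[j])
      if (abs(t0[i] - t0[j]) <= m && abs(tEnd[i] - tEnd[j]) <= m) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Distill cognate candidates into real events
#'
#' Two candidates are cognates — detections of the same underlying event at
#' different timescales — if their start and end times agree within a
#' tolerance of 20\% of the halfwidth (the larger of the pair). Cognates are
#' merged transitively (single linkage). For each cognate set the start and
#' end time of the real event are estimated as medians over the set, and the
#' halfwidth as their difference.
#'
#' Sets are then filtered: an event with halfwidth above 2 s must consist of
#' at least four candidates (detectable at timescales differing at least
#' twofold); a shorter event must not be unique to a single timescale (at
#' least two candidates). Events lasting less than \code{minFrames} frame
#' periods, or lying within half their halfwidth of either end of the
#' recording (where filter edge artifacts live), are dropped.
#'
#' @param cands Candidate table from [multiscaleScan()] (one ROI). May carry a
#'   \code{roi} column, in which case ROIs are distilled independently.
#' @param frameRate Sampling rate in Hz (for the three-frame rule).
#' @param duration Recording duration in seconds (for the edge rule).
#' @param tol Cognate tolerance as a fraction of the halfwidth (default 0.2).
#' @param minFrames Minimum event duration in frame periods (default 3).
#' @param nScalesLong Minimum candidates for events longer than
#'   \code{longBound} (default 4).
#' @param longBound Halfwidth (s) above which the stricter rule applies
#'   (default 2).
#' @return \code{data.frame(t0_s, t_end_s, halfwidth_s, z_max, n_scales,
#'   n_tau, tau_min_s, tau_max_s)} sorted by \code{t0_s} (plus \code{roi} if
#'   present in the input).
#' @export
distillEvents <- function(cands, frameRate, duration, tol = 0.2,
                          minFrames = 3L, nScalesLong = 4L, longBound = 2) {
  emptyOut <- data.frame(t0_s = numeric(), t_end_s = numeric(),
                         halfwidth_s = numeric(), z_max = numeric(),
                         n_scales = integer(), n_tau = integer(),
                         tau_min_s = numeric(), tau_max_s = numeric())
  if ("roi" %in% names(cands)) {
    parts <- lapply(split(cands, cands$roi), function(p) {
      out <- distillEvents(p[setdiff(names(p), "roi")], frameRate, duration,
                           tol, minFrames, nScalesLong, longBound)
      if (nrow(out)) cbind(roi = p$roi[1L], out) else NULL
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) return(cbind(roi = integer(), emptyOut))
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    return(out)
  }
  if (!nrow(cands)) return(emptyOut)
  comp <- .cognateComponents(cands$t0_s, cands$t_end_s, cands$halfwidth_s, tol)
  sets <- split(seq_len(nrow(cands)), comp)
  rows <- lapply(sets, function(ix) {
    t0 <- stats::median(cands$t0_s[ix])
    tEnd <- stats::median(cands$t_end_s[ix])
    hw <- tEnd - t0
    tau <- if ("tau_s" %in% names(cands)) cands$tau_s[ix] else NA_real_
    data.frame(t0_s = t0, t_end_s = tEnd, halfwidth_s = hw,
               z_max = max(cands$z_max[ix]), n_scales = length(ix),
               n_tau = length(unique(tau)),
               tau_min_s = min(tau), tau_max_s = max(tau))
  })
  out <- do.call(rbind, rows)
  need <- ifelse(out$halfwidth_s > longBound, as.integer(nScalesLong), 2L)
  keep <- out$n_scales >= need &
    out$halfwidth_s >= minFrames / frameRate &
    out$t0_s >= out$halfwidth_s / 2 &
    out$t_end_s <= duration - out$halfwidth_s / 2
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$t0_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect and distill events for every ROI of a movie
#'
#' @param traces Matrix of summed ROI traces from [roiTraces()] (columns =
#'   ROIs).
#' @param frameRate Sampling rate in Hz.
#' @param ladder,zThresh,nIter,zOut,gain Passed to [multiscaleScan()].
#' @param tol,minFrames Passed to [distillEvents()].
#' @return List with \code{candidates} and \code{events} data frames, each
#'   with a \code{roi} column.
#' @export
detectEvents <- function(traces, frameRate, ladder = timescaleLadder(),
                         zThresh = 4, nIter = 3L, zOut = 3, gain = 1,
                         tol = 0.2, minFrames = 3L) {
  stopifnot(is.matrix(traces))
  labs <- colnames(traces)
  if (is.null(labs)) labs <- as.character(seq_len(ncol(traces)))
  duration <- nrow(traces) / frameRate
  cand <- lapply(seq_len(ncol(traces)), function(j) {
    cc <- multiscaleScan(traces[, j], frameRate, ladder, zThresh,
                         nIter, zOut, gain)
    if (nrow(cc)) cbind(roi = as.integer(labs[j]), cc) else NULL
  })
  cand <- cand[!vapply(cand, is.null, logical(1))]
  candidates <- if (length(cand)) do.call(rbind, cand) else
    cbind(roi = integer(),
          data.frame(tau_s = numeric(), t0_s = numeric(), t_end_s = numeric(),
                     halfwidth_s = numeric(), height = numeric(),
                     z_max = numeric()))
  rownames(candidates) <- NULL
  events <- distillEvents(candidates, frameRate, duration, tol, minFrames)
  list(candidates = candidates, events = events)
}
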