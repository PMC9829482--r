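#' @include AllClasses.R
NULL

#' Classify events by halfwidth duration
#'
#' Events separate into three duration classes — ultra-short, short and long —
#' with boundaries at 2 s and 8.5 s: ultra-short < 2 s <= short < 8.5 s <=
#' long.
#'
#' @param events Event table with a \code{halfwidth_s} column.
#' @param bounds Numeric length-2 class boundaries in seconds
#'   (default \code{c(2, 8.5)}).
#' @return \code{events} with an added factor column \code{class}.
#' @export
classifyEvents <- function(events, bounds = c(2, 8.5)) {
  stopifnot(is.data.frame(events), "halfwidth_s" %in% names(events),
            length(bounds) == 2L, bounds[1L] > 0, bounds[1L] < bounds[2L])
  if (nrow(events) && any(events$halfwidth_s <= 0))
    stop("halfwidths must be positive")
  events$class <- cut(events$halfwidth_s, c(0, bounds, Inf),
                      labels = c("ultra_short", "short", "long"),
                      right = FALSE)
  events
}

#' Gaussian fit of the logarithmic halfwidth distribution
#'
#' Histograms \code{log10(halfwidth)} (bin width 0.1 dex by default) and fits
#' a K-component sum of Gaussians to the density by least squares, with a
#' deterministic multi-start initialized from data quantiles. With the
#' default K = 3 this captures the tri-modal structure of ultra-short, short
#' and long events.
#'
#' @param halfwidths Numeric vector of halfwidths in seconds (or an event
#'   table with a \code{halfwidth_s} column). At least \code{10 * K} values.
#' @param K Number of Gaussian modes (default 3).
#' @param binWidth Histogram bin width in dex (default 0.1).
#' @return List of class \code{"logGaussFit"}: \code{modes} (data frame with
#'   \code{weight}, \code{mean_log10_s}, \code{sd_log10_s}, ordered by mean),
#'   \code{ssr} (sum of squared density residuals), \code{hist} (mids,
#'   density).
#' @export
fitLogHalfwidth <- function(halfwidths, K = 3L, binWidth = 0.1) {
  if (is.data.frame(halfwidths)) halfwidths <- halfwidths$halfwidth_s
  halfwidths <- halfwidths[is.finite(halfwidths) & halfwidths > 0]
  K <- as.integer(K)
  if (length(halfwidths) < 10L * K)
    stop("need at least ", 10L * K, " events for a ", K, "-mode fit, got ",
         length(halfwidths))
  lx <- log10(halfwidths)
  br <- seq(floor(min(lx) / binWidth) * binWidth - binWidth,
            ceiling(max(lx) / binWidth) * binWidth + binWidth,
            by = binWidth)
  h <- graphics::hist(lx, breaks = br, plot = FALSE)
  xs <- h$mids
  ys <- h$density

  modelY <- function(p) {
    a <- exp(p[1:K]); m <- p[(K + 1):(2 * K)]; s <- exp(p[(2 * K + 1):(3 * K)])
    y <- 0
    for (k in seq_len(K)) y <- y + a[k] * stats::dnorm(xs, m[k], s[k])
    y
  }
  ssrOf <- function(p) sum((ys - modelY(p))^2)

  qs <- stats::quantile(lx, probs = (2 * seq_len(K) - 1) / (2 * K),
                        names = FALSE, type = 7)
  spread <- diff(range(lx))
  starts <- list(
    c(rep(log(1 / K), K), qs, rep(log(0.15), K)),
    c(rep(log(1 / K), K),
      seq(min(lx) + spread / (2 * K), max(lx) - spread / (2 * K),
          length.out = K), rep(log(0.2), K)),
    c(rep(log(1 / K), K), qs, rep(log(0.08), K))
  )
  fits <- lapply(starts, function(p0)
    stats::optim(p0, ssrOf, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p <- best$par
  a <- exp(p[1:K])
  modes <- data.frame(weight = a / sum(a),
                      mean_log10_s = p[(K + 1):(2 * K)],
                      sd_log10_s = exp(p[(2 * K + 1):(3 * K)]))
  modes <- modes[order(modes$mean_log10_s), , drop = FALSE]
  rownames(modes) <- NULL
  structure(list(modes = modes, ssr = best$value,
                 hist = data.frame(mid = xs, density = ys), K = K),
            class = "logGaussFit")
}

#' @export
print.logGaussFit <- function(x, ...) {
  cat(sprintf("%d-mode Gaussian fit of log10 halfwidth (SSR %.4g)\n",
              x$K, x$ssr))
  m <- x$modes
  for (i in seq_len(nrow(m)))
    cat(sprintf("  mode %d: center %.2f dex (%.2g s), sd %.2f dex, weight %.2f\n",
                i, m$mean_log10_s[i], 10^m$mean_log10_s[i], m$sd_log10_s[i],
                m$weight[i]))
  invisible(x)
}

#' Filter inactive ROIs by high-pass event count
#'
#' ROIs are screened by the number of events found in their trace after
#' high-pass filtering at 0.2 Hz (i.e. candidate detection at the 5 s
#' timescale); ROIs with fewer than \code{minEvents} events are discarded.
#' The count histogram is returned so the threshold can be inspected.
#'
#' @param counts Named integer vector (names = ROI labels) of per-ROI event
#'   counts from [activityCounts()], or a data frame with columns \code{roi}
#'   and \code{count}.
#' @param minEvents Minimum number of events to retain a ROI.
#' @return List with \code{retained} (labels), \code{counts},
#'   \code{histogram} (table of counts) and \code{threshold}.
#' @export
roiActivityFilter <- function(counts, minEvents = 1L) {
  if (is.data.frame(counts)) {
    v <- counts$count
    names(v) <- counts$roi
    counts <- v
  }
  keep <- counts >= minEvents
  list(retained = names(counts)[keep], counts = counts,
       histogram = table(counts), threshold = minEvents)
}

#' Per-ROI event counts at a fixed high-pass cutoff
#'
#' @param traces Matrix of summed ROI traces (columns = ROIs).
#' @param frameRate Sampling rate in Hz.
#' @param fCut High-pass cutoff in Hz (default 0.2: events faster than 5 s).
#' @param zThresh,nIter,gain Passed to [zscoreTrace()] / [detectCandidates()].
#' @return Named integer vector of event counts.
#' @export
activityCounts <- function(traces, frameRate, fCut = 0.2, zThresh = 4,
                           nIter = 3L, gain = 1) {
  stopifnot(is.matrix(traces))
  labs <- colnames(traces)
  if (is.null(labs)) labs <- as.character(seq_len(ncol(traces)))
  n <- vapply(seq_len(ncol(traces)), function(j) {
    zs <- zscoreTrace(traces[, j], frameRate, fCut = fCut, nIter = nIter,
                      gain = gain)
    nrow(detectCandidates(zs, zThresh = zThresh))
  }, integer(1))
  names(n) <- labs
  n
}

#' Event rate in tiling windows
#'
#' @param events Event table with \code{t0_s}.
#' @param duration Recording duration in seconds.
#' @param window Window length in seconds (default 60). Windows tile the
#'   recording, so the counts sum back to the total number of events whose
#'   start lies inside the recording.
#' @return \code{data.frame(t_mid_s, count, rate_per_min)}.
#' @export
eventRate <- function(events, duration, window = 60) {
  nW <- max(1L, as.integer(ceiling(duration / window - 1e-9)))
  starts <- (seq_len(nW) - 1L) * window
  counts <- vapply(starts, function(s)
    sum(events$t0_s >= s & events$t0_s < s + window), numeric(1))
  data.frame(t_mid_s = starts + window / 2, count = counts,
             rate_per_min = counts / (window / 60))
}

#' Empirical CDF of event halfwidths
#'
#' @param events Event table with \code{halfwidth_s} (or a numeric vector).
#' @return An \code{ecdf} function.
#' @export
halfwidthCdf <- function(events) {
  hw <- if (is.data.frame(events)) events$halfwidth_s else events
  stopifnot(length(hw) > 0)
  stats::ecdf(hw)
}

#' Count short events contained in each long event
#'
#' A short event is contained in a long one iff its \code{[t0, t_end]}
#' interval lies entirely inside the long event's interval. Long events built
#' by temporal summation of (ultra-)short transients show substructure as a
#' positive containment count.
#'
#' @param longEvents,shortEvents Event tables with \code{t0_s}, \code{t_end_s}.
#' @return Integer vector, one count per long event.
#' @export
containmentCount <- function(longEvents, shortEvents) {
  vapply(seq_len(nrow(longEvents)), function(i)
    sum(shortEvents$t0_s >= longEvents$t0_s[i] &
        shortEvents$t_end_s <= longEvents$t_end_s[i]), integer(1))
}

#' Rank-based comparison of two halfwidth samples
#'
#' Reports medians and quartiles (linear-interpolation, type-7 quantiles —
#' the values depend on this convention) per group and a two-sided
#' Mann-Whitney U (Wilcoxon rank-sum) P value.
#'
#' @param groupA,groupB Numeric halfwidth vectors (non-empty).
#' @return \code{data.frame} with one row per group (\code{median},
#'   \code{q1}, \code{q3}, \code{n}) and attribute \code{p.value}; also
#'   returned in the list element \code{p.value}.
#' @export
compareHalfwidths <- function(groupA, groupB) {
  stopifnot(length(groupA) > 0, length(groupB) > 0)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                                    type = 7)
  a <- qs(groupA); b <- qs(groupB)
  p <- stats::wilcox.test(groupA, groupB, exact = FALSE)$p.value
  list(summary = data.frame(group = c("A", "B"),
                            median = c(a[2L], b[2L]),
                            q1 = c(a[1L], b[1L]), q3 = c(a[3L], b[3L]),
                            n = c(length(groupA), length(groupB))),
       p.value = p)
}
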