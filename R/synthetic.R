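#' @include AllClasses.R
NULL

# Unitary transient kernel: difference of exponentials, rise 50 ms and decay
# 300 ms by default, normalized to unit peak. Its own halfwidth is just under
# 0.3 s, so unitary events land in the ultra-short class.
.unitaryKernel <- function(fs, rise = 0.05, decay = 0.3) {
  t <- seq(0, rise + 8 * decay, by = 1 / fs)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

# Interpolated half-maximum crossings of a noiseless waveform.
# Returns c(t0, tEnd) in seconds relative to the first sample.
.waveformHalfwidth <- function(w, fs) {
  ipk <- which.max(w)
  half <- w[ipk] / 2
  j <- ipk
  while (j > 1L && w[j - 1L] >= half) j <- j - 1L
  t0 <- if (j == 1L) 0 else
    (j - 2L + (half - w[j - 1L]) / (w[j] - w[j - 1L])) / fs
  j <- ipk
  while (j < length(w) && w[j + 1L] >= half) j <- j + 1L
  tEnd <- if (j == length(w)) (length(w) - 1L) / fs else
    (j - 1L + (w[j] - half) / (w[j] - w[j + 1L])) / fs
  c(t0, tEnd)
}

# Compound event waveform: a dense train of unitary transients, built as a
# plateau (boxcar) convolved with the unitary kernel, the limiting case of
# temporal summation. The plateau length is solved so that the waveform's
# half-maximum width matches the requested halfwidth; below the unitary
# kernel's own halfwidth the bare kernel is returned.
.eventWaveform <- function(fs, halfwidth, rise = 0.05, decay = 0.3) {
  kern <- .unitaryKernel(fs, rise, decay)
  build <- function(L) {
    nL <- max(1L, as.integer(round(L * fs)))
    w <- stats::convolve(rep(1, nL), rev(kern), type = "open")
    w / max(w)
  }
  h0 <- diff(.waveformHalfwidth(kern, fs))
  if (halfwidth <= h0 + 0.25 / fs) {
    w <- kern
  } else {
    f <- function(L) diff(.waveformHalfwidth(build(L), fs)) - halfwidth
    up <- halfwidth * 1.5 + 1
    L <- stats::uniroot(f, c(1 / fs / 4, up), tol = 1 / (8 * fs))$root
    w <- build(L)
  }
  cross <- .waveformHalfwidth(w, fs)
  list(w = w, t0_off = cross[1L], t_end_off = cross[2L],
       halfwidth = diff(cross))
}

#' Simulate a photon-counting trace with planted events
#'
#' Builds a noiseless intensity \eqn{\lambda(t)} = baseline plus one compound
#' waveform per planted event (a plateau of summated unitary transients whose
#' half-maximum width matches the requested halfwidth), then draws each
#' sample as an independent Poisson count (times \code{gain}). Event
#' amplitudes are set so the ideal peak z-score equals \code{z_max}:
#' amplitude = \code{z_max * sqrt(baseline)} in intensity units.
#'
#' @param duration Recording length in seconds.
#' @param frameRate Sampling rate in Hz (default 20, the acquisition rate the
#'   generator emulates).
#' @param baseline Baseline intensity in counts/frame (default 100).
#' @param events \code{data.frame(t0_s, halfwidth_s, z_max)} of planted
#'   events (\code{t0_s} is the intended half-maximum start time), or NULL
#'   for pure noise.
#' @param gain Detector variance/mean slope (default 1).
#' @param rise,decay Unitary transient kernel time constants in seconds.
#' @param seed RNG seed; a fixed seed gives a bit-identical trace.
#' @return List: \code{x} (counts), \code{lambda} (noiseless intensity),
#'   \code{truth} (planted events with the realised half-maximum times
#'   \code{t0_s}, \code{t_end_s}, \code{halfwidth_s}, the duration
#'   \code{class}, and \code{z_max}), \code{frameRate}, \code{duration}.
#' @seealso [simulateMovie()]
#' @export
simulateTrace <- function(duration, frameRate = 20, baseline = 100,
                          events = NULL, gain = 1, rise = 0.05, decay = 0.3,
                          seed = 1L) {
  n <- as.integer(round(duration * frameRate))
  lambda <- rep(as.numeric(baseline), n)
  truth <- data.frame(t0_s = numeric(), t_end_s = numeric(),
                      halfwidth_s = numeric(), class = character(),
                      z_max = numeric())
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ev <- .eventWaveform(frameRate, events$halfwidth_s[i], rise, decay)
      i0 <- as.integer(round((events$t0_s[i] - ev$t0_off) * frameRate)) + 1L
      idx <- i0:(i0 + length(ev$w) - 1L)
      ok <- idx >= 1L & idx <= n
      amp <- events$z_max[i] * sqrt(baseline)
      lambda[idx[ok]] <- lambda[idx[ok]] + amp * ev$w[ok]
      tStart <- (i0 - 1L) / frameRate
      truth <- rbind(truth, data.frame(
        t0_s = tStart + ev$t0_off, t_end_s = tStart + ev$t_end_off,
        halfwidth_s = ev$halfwidth,
        class = as.character(cut(ev$halfwidth, c(0, 2, 8.5, Inf),
                                 c("ultra_short", "short", "long"),
                                 right = FALSE)),
        z_max = events$z_max[i]))
    }
  }
  x <- .withSeed(seed, gain * stats::rpois(n, lambda))
  list(x = as.numeric(x), lambda = lambda, truth = truth,
       frameRate = frameRate, duration = n / frameRate)
}

#' Simulation configuration for synthetic islet movies
#'
#' Defaults emulate the recordings the pipeline is built for: 20 Hz,
#' 256 x 256 px at 1 um^2/px photon-counting movies of ~10 um disk-shaped
#' islet cells on a dim background, whose transients summate into
#' ultra-short, short and long events.
#'
#' @param fovPx Field of view in pixels (rows, cols).
#' @param pixelSizeUm Pixel size in micrometres.
#' @param frameRate Frame rate in Hz.
#' @param duration Recording length in seconds.
#' @param nCells Number of cells.
#' @param cellDiameterUm Cell diameter in micrometres.
#' @param baselineRate Background intensity, counts/px/frame.
#' @param cellBrightness Extra resting intensity inside cells,
#'   counts/px/frame.
#' @param gain Detector variance/mean slope.
#' @param rise,decay Unitary transient kernel time constants (s).
#' @param events Event plan: \code{"trimodal"} (random tri-modal plan),
#'   \code{"none"}, or a \code{data.frame(cell, t0_s, halfwidth_s, z_max)}.
#' @param silentFraction With the \code{"trimodal"} plan, fraction of cells
#'   left without events.
#' @param drift Optional \code{data.frame(frame, dy, dx)} of integer drift
#'   applied to the scene before sampling.
#' @param seed RNG seed.
#' @return A list of class \code{"SimConfig"}.
#' @export
simConfig <- function(fovPx = c(256L, 256L), pixelSizeUm = 1, frameRate = 20,
                      duration = 60, nCells = 30L, cellDiameterUm = 10,
                      baselineRate = 2, cellBrightness = 8, gain = 1,
                      rise = 0.05, decay = 0.3, events = "trimodal",
                      silentFraction = 0, drift = NULL, seed = 1L) {
  cfg <- list(fovPx = as.integer(fovPx), pixelSizeUm = pixelSizeUm,
              frameRate = frameRate, duration = duration,
              nCells = as.integer(nCells), cellDiameterUm = cellDiameterUm,
              baselineRate = baselineRate, cellBrightness = cellBrightness,
              gain = gain, rise = rise, decay = decay, events = events,
              silentFraction = silentFraction, drift = drift,
              seed = as.integer(seed))
  stopifnot(cfg$baselineRate >= 0, cfg$cellBrightness >= 0,
            cfg$frameRate > 0, cfg$duration > 0)
  r <- cellDiameterUm / 2 / pixelSizeUm
  if (2 * (r + 2) > min(cfg$fovPx))
    stop("infeasible geometry: cells do not fit in the field of view")
  class(cfg) <- "SimConfig"
  cfg
}

# Random non-overlapping cell placement (rejection sampling).
.placeCells <- function(fov, n, radius, minSep) {
  margin <- radius + 2
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    p <- c(stats::runif(1, margin, fov[1L] - margin),
           stats::runif(1, margin, fov[2L] - margin))
    if (!nrow(pts) || all(sqrt((pts[, 1] - p[1])^2 +
                               (pts[, 2] - p[2])^2) >= minSep))
      pts <- rbind(pts, p)
    tries <- tries + 1L
    if (tries > 2000L * n)
      stop("infeasible geometry: could not place ", n, " cells")
  }
  pts
}

# Tri-modal event plan: per active cell, events drawn from the three duration
# modes (log-normal around 0.5, 3 and 20 s, sd 0.12 dex), start times uniform
# with edge clearance, peak z between 7 and 9.
.planTrimodal <- function(cfg) {
  active <- seq_len(cfg$nCells)
  nSilent <- as.integer(round(cfg$silentFraction * cfg$nCells))
  if (nSilent > 0L) active <- active[seq_len(cfg$nCells - nSilent)]
  plans <- lapply(active, function(ci) {
    hw <- sampleTrimodalHalfwidths(sample(2:4, 1L))
    # keep events whose halfwidth and edge clearance fit the recording
    hw <- hw[3 * hw + 6 < cfg$duration]
    if (!length(hw)) return(NULL)
    t0 <- vapply(hw, function(h)
      stats::runif(1, h + 2, cfg$duration - 2 * h - 2), numeric(1))
    ord <- order(t0)
    data.frame(cell = ci, t0_s = t0[ord], halfwidth_s = hw[ord],
               z_max = stats::runif(length(hw), 7, 9))
  })
  do.call(rbind, plans[!vapply(plans, is.null, logical(1))])
}

#' Sample halfwidths from the tri-modal duration distribution
#'
#' Log-normal modes centered at 0.5, 3 and 20 s (sd 0.12 dex by default),
#' one mode per duration class (ultra-short/short/long).
#'
#' @param n Number of samples.
#' @param centers Mode centers in seconds.
#' @param sdDex Mode standard deviation in dex.
#' @param weights Mode weights (normalized internally).
#' @param seed Optional seed; NULL uses the current RNG state.
#' @return Numeric vector of halfwidths in seconds.
#' @export
sampleTrimodalHalfwidths <- function(n, centers = c(0.5, 3, 20), sdDex = 0.12,
                                     weights = c(1, 1, 1), seed = NULL) {
  draw <- function() {
    k <- sample.int(length(centers), n, replace = TRUE,
                    prob = weights / sum(weights))
    10^(log10(centers[k]) + stats::rnorm(n, 0, sdDex))
  }
  if (is.null(seed)) draw() else .withSeed(seed, draw())
}

#' Simulate a ground-truthed photon-counting islet movie
#'
#' Disk-shaped cells (soft 1 px edge) are placed without overlap; every
#' pixel's intensity is baseline plus the cell's resting brightness plus the
#' cell's event waveforms, scaled so the planted peak z-score on the summed
#' ROI trace matches the plan. Frames are independent Poisson draws of the
#' intensity (times \code{gain}); optional rigid drift shifts the scene
#' before sampling. Fixed seed gives bit-identical output.
#'
#' @param cfg A [simConfig()].
#' @return List: \code{movie} (a \linkS4class{CaMovie}) and \code{truth}
#'   (list with \code{cells}, \code{events} — realised half-maximum times per
#'   planted event — and \code{drift}).
#' @export
simulateMovie <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  .withSeed(cfg$seed, {
    fov <- cfg$fovPx
    fs <- cfg$frameRate
    nT <- as.integer(round(cfg$duration * fs))
    r <- cfg$cellDiameterUm / 2 / cfg$pixelSizeUm
    centers <- .placeCells(fov, cfg$nCells, r, minSep = 2 * r + 1)
    cells <- data.frame(cell = seq_len(cfg$nCells),
                        row = centers[, 1L], col = centers[, 2L],
                        radius_px = r)

    # per-cell soft-edged disk masks, bounding boxes
    masks <- lapply(seq_len(cfg$nCells), function(ci) {
      r0 <- max(1L, as.integer(floor(centers[ci, 1] - r - 1)))
      r1 <- min(fov[1L], as.integer(ceiling(centers[ci, 1] + r + 1)))
      c0 <- max(1L, as.integer(floor(centers[ci, 2] - r - 1)))
      c1 <- min(fov[2L], as.integer(ceiling(centers[ci, 2] + r + 1)))
      dd <- sqrt(outer((r0:r1 - centers[ci, 1])^2,
                       (c0:c1 - centers[ci, 2])^2, `+`))
      m <- pmin(1, pmax(0, r + 0.5 - dd))
      list(rows = r0:r1, cols = c0:c1, m = m, sum = sum(m))
    })

    base <- matrix(cfg$baselineRate, fov[1L], fov[2L])
    for (ci in seq_len(cfg$nCells)) {
      mk <- masks[[ci]]
      base[mk$rows, mk$cols] <- base[mk$rows, mk$cols] + cfg$cellBrightness * mk$m
    }

    plan <- cfg$events
    if (identical(plan, "trimodal")) plan <- .planTrimodal(cfg)
    if (identical(plan, "none")) plan <- NULL

    # per-cell time-varying amplitude traces (counts/unit-mask/frame) + truth
    amp <- matrix(0, nT, cfg$nCells)
    truth <- NULL
    if (!is.null(plan) && nrow(plan)) {
      for (i in seq_len(nrow(plan))) {
        ci <- plan$cell[i]
        mk <- masks[[ci]]
        # amplitude on the SUMMED ROI trace giving peak z = z_max; in
        # intensity units the gain cancels (z is gain-corrected downstream)
        muSum <- sum(base[mk$rows, mk$cols] * (mk$m > 0))
        aSum <- plan$z_max[i] * sqrt(muSum)
        ev <- .eventWaveform(fs, plan$halfwidth_s[i], cfg$rise, cfg$decay)
        i0 <- as.integer(round((plan$t0_s[i] - ev$t0_off) * fs)) + 1L
        idx <- i0:(i0 + length(ev$w) - 1L)
        ok <- idx >= 1L & idx <= nT
        amp[idx[ok], ci] <- amp[idx[ok], ci] + aSum * ev$w[ok] / mk$sum
        tStart <- (i0 - 1L) / fs
        truth <- rbind(truth, data.frame(
          cell = ci, t0_s = tStart + ev$t0_off,
          t_end_s = tStart + ev$t_end_off, halfwidth_s = ev$halfwidth,
          class = as.character(cut(ev$halfwidth, c(0, 2, 8.5, Inf),
                                   c("ultra_short", "short", "long"),
                                   right = FALSE)),
          z_max = plan$z_max[i]))
      }
    }
    if (is.null(truth))
      truth <- data.frame(cell = integer(), t0_s = numeric(),
                          t_end_s = numeric(), halfwidth_s = numeric(),
                          class = character(), z_max = numeric())

    drift <- cfg$drift
    data <- array(0, c(nT, fov[1L], fov[2L]))
    activeCells <- which(colSums(amp) > 0)
    for (t in seq_len(nT)) {
      lam <- base
      for (ci in activeCells) {
        if (amp[t, ci] > 0) {
          mk <- masks[[ci]]
          lam[mk$rows, mk$cols] <- lam[mk$rows, mk$cols] + amp[t, ci] * mk$m
        }
      }
      if (!is.null(drift)) {
        i <- match(t, drift$frame)
        if (!is.na(i) && (drift$dy[i] != 0 || drift$dx[i] != 0))
          lam <- .shiftMatrix(lam, drift$dy[i], drift$dx[i],
                              fill = cfg$baselineRate)
      }
      data[t, , ] <- cfg$gain * stats::rpois(length(lam), lam)
    }
    list(movie = CaMovie(data, frameRate = fs, pixelSize = cfg$pixelSizeUm,
                         gain = cfg$gain),
         truth = list(cells = cells, events = truth, drift = drift))
  })
}
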