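#' @include AllClasses.R
NULL

#' Default pipeline configuration
#'
#' All defaults mirror the analysis constants the pipeline is built around:
#' detection ladder from 0.5 s with ratio 2^(1/4), z > 4, 20\% cognate
#' tolerance, 3-frame minimum, class bounds 2 s and 8.5 s, activity screen at
#' 0.2 Hz, 10 um cell kernel.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list (a pipeline configuration).
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    input = NULL,              # path to a multipage TIFF, or "simulate"
    frame_rate_hz = 20,
    pixel_size_um = 1,
    gain = 1,                  # or "auto" to calibrate from the movie
    motion_correct = FALSE,
    work_rate_hz = 2,
    statistic = "representative",
    kernel_um = 10,
    bp_threshold = 0,
    min_size_px = 4,
    tau_min_s = 0.5,
    tau_max_s = 128,
    z_thresh = 4,
    n_iter = 3,
    tol = 0.2,
    min_frames = 3,
    class_bounds_s = c(2, 8.5),
    activity_fcut_hz = 0.2,
    min_events = 1,
    sim = list(),              # overrides for simConfig() when input="simulate"
    seed = 1,
    out_dir = "caevents-out"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip losslessly through the YAML file.
#'
#' @param path YAML file path.
#' @return For \code{readPipelineConfig}, the configuration list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' @rdname readPipelineConfig
#' @param cfg Configuration list from [pipelineConfig()].
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full detection pipeline
#'
#' Orchestrates the stages end to end: load (or simulate) the movie,
#' optionally motion-correct, compute the representative image, segment into
#' ROIs, extract summed traces, scan the timescale ladder for candidates,
#' distill them into events, screen ROI activity at 0.2 Hz, classify events,
#' and write the artifact bundle: ROI table (+ label image), traces,
#' candidate and event tables, a JSON summary echoing every stage's
#' parameters, and a log. Deterministic given the configuration and seed.
#'
#' @param cfg Configuration from [pipelineConfig()] /
#'   [readPipelineConfig()], or a path to a YAML config.
#' @return Invisibly, a list with the in-memory results (\code{movie},
#'   \code{rois}, \code{traces}, \code{candidates}, \code{events},
#'   \code{activity}, \code{outDir}).
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- readPipelineConfig(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$out_dir, "pipeline.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon))
  say <- function(stage, ...) {
    writeLines(sprintf("[%s] %s", stage, paste0(...)), logCon)
  }
  fail <- function(stage, e) stop("pipeline stage [", stage, "]: ",
                                  conditionMessage(e), call. = FALSE)

  # --- load / simulate -------------------------------------------------
  truth <- NULL
  movie <- tryCatch({
    if (identical(cfg$input, "simulate")) {
      sim <- do.call(simConfig, utils::modifyList(
        list(frameRate = cfg$frame_rate_hz, pixelSizeUm = cfg$pixel_size_um,
             seed = cfg$seed), cfg$sim))
      say("load", "simulating movie (seed ", sim$seed, ")")
      res <- simulateMovie(sim)
      truth <- res$truth
      res$movie
    } else {
      if (is.null(cfg$input) || !file.exists(cfg$input))
        stop("input movie not found: ", cfg$input)
      say("load", "reading ", cfg$input)
      loadMovie(cfg$input, cfg$frame_rate_hz, cfg$pixel_size_um,
                gain = if (identical(cfg$gain, "auto")) 1 else cfg$gain)
    }
  }, error = function(e) fail("load", e))

  gain <- tryCatch({
    if (identical(cfg$gain, "auto")) {
      g <- calibrateGain(movie)
      say("gain", sprintf("calibrated gain = %.3f", g))
      g
    } else cfg$gain
  }, error = function(e) fail("gain", e))

  if (isTRUE(cfg$motion_correct)) {
    movie <- tryCatch({
      off <- estimateMotion(movie, workRate = cfg$work_rate_hz)
      writeOffsets(off, file.path(cfg$out_dir, "offsets.csv"))
      say("motion", sprintf("max |offset| = %d px",
                            max(abs(c(off$dy, off$dx)))))
      applyMotion(movie, off)
    }, error = function(e) fail("motion", e))
  }

  # --- segmentation ----------------------------------------------------
  rois <- tryCatch({
    r <- segmentMovie(movie, kernelUm = cfg$kernel_um,
                      statistic = cfg$statistic,
                      threshold = cfg$bp_threshold,
                      minSize = cfg$min_size_px)
    say("segment", nRois(r), " ROIs")
    if (!nRois(r)) stop("no ROIs found")
    writeRoiTable(r, file.path(cfg$out_dir, "rois.csv"),
                  file.path(cfg$out_dir, "labels.tif"))
    r
  }, error = function(e) fail("segment", e))

  traces <- tryCatch({
    tr <- roiTraces(movie, rois)
    df <- data.frame(frame = seq_len(nrow(tr)),
                     time_s = (seq_len(nrow(tr)) - 1) / frameRate(movie), tr,
                     check.names = FALSE)
    utils::write.csv(df, file.path(cfg$out_dir, "traces.csv"),
                     row.names = FALSE)
    tr
  }, error = function(e) fail("traces", e))

  # --- detection -------------------------------------------------------
  duration <- nFrames(movie) / frameRate(movie)
  tauMax <- cfg$tau_max_s
  if (tauMax >= duration) {
    tauMax <- duration / 2
    say("detect", sprintf(
      "tau_max %.3g s >= recording (%.3g s); ladder trimmed to %.3g s",
      cfg$tau_max_s, duration, tauMax))
  }
  det <- tryCatch({
    ladder <- timescaleLadder(tauMax = tauMax, tauMin = cfg$tau_min_s)
    d <- detectEvents(traces, frameRate(movie), ladder = ladder,
                      zThresh = cfg$z_thresh, nIter = cfg$n_iter, gain = gain,
                      tol = cfg$tol, minFrames = cfg$min_frames)
    say("detect", nrow(d$candidates), " candidates -> ",
        nrow(d$events), " distilled events")
    d
  }, error = function(e) fail("detect", e))

  events <- tryCatch({
    ev <- classifyEvents(det$events, bounds = cfg$class_bounds_s)
    utils::write.csv(det$candidates,
                     file.path(cfg$out_dir, "candidates.csv"),
                     row.names = FALSE)
    utils::write.csv(ev, file.path(cfg$out_dir, "events.csv"),
                     row.names = FALSE)
    ev
  }, error = function(e) fail("classify", e))

  activity <- tryCatch({
    counts <- activityCounts(traces, frameRate(movie),
                             fCut = cfg$activity_fcut_hz,
                             zThresh = cfg$z_thresh, gain = gain)
    flt <- roiActivityFilter(counts, minEvents = cfg$min_events)
    say("activity", length(flt$retained), " of ", length(counts),
        " ROIs retained at >= ", cfg$min_events, " events (0.2 Hz screen)")
    flt
  }, error = function(e) fail("activity", e))

  summary <- list(
    parameters = cfg[setdiff(names(cfg), "sim")],
    gain = gain,
    movie = list(frames = nFrames(movie), shape = dim(movie)[2:3],
                 frame_rate_hz = frameRate(movie),
                 pixel_size_um = pixelSize(movie), duration_s = duration),
    n_rois = nRois(rois),
    n_candidates = nrow(det$candidates),
    n_events = nrow(events),
    events_by_class = as.list(table(events$class)),
    rois_retained = length(activity$retained)
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done", "bundle written to ", cfg$out_dir)

  invisible(list(movie = movie, rois = rois, traces = traces,
                 candidates = det$candidates, events = events,
                 activity = activity, truth = truth, outDir = cfg$out_dir))
}
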