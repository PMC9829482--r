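#' @include AllClasses.R
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Zero-phase second-order-section (biquad) Butterworth low-pass.
# The signal is padded by edge replication (~6/W samples) before the
# forward-backward pass so that the filter state has converged by the time it
# reaches the data; without padding the start-up transient from the zero
# initial state corrupts the slow component over ~1/W samples.
.lowpass <- function(x, fCutHz, fsHz, zeroPhase = TRUE) {
  W <- fCutHz / (fsHz / 2)
  if (!is.finite(W) || W <= 0 || W >= 1)
    stop("cutoff must satisfy 0 < fCut < Nyquist (fCut = ", fCutHz,
         " Hz at ", fsHz, " Hz)")
  bf <- signal::butter(2, W, type = "low")
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(6 / W)))
  xp <- c(rep(x[1L], pad), x, rep(x[n], pad))
  y <- if (zeroPhase) signal::filtfilt(bf, xp)
       else as.numeric(signal::filter(bf, xp))
  y[(pad + 1L):(pad + n)]
}

# Shift a matrix by integer (dy, dx); vacated pixels are filled with `fill`.
.shiftMatrix <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  srcR <- seq_len(nr); srcR <- srcR[srcR + dy >= 1 & srcR + dy <= nr]
  srcC <- seq_len(nc); srcC <- srcC[srcC + dx >= 1 & srcC + dx <= nc]
  if (length(srcR) && length(srcC))
    out[srcR + dy, srcC + dx] <- m[srcR, srcC]
  out
}

.assertScalar <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.finite(x) || (positive && x <= 0))
    stop(name, " must be a single finite", if (positive) " positive", " number")
  invisible(x)
}
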