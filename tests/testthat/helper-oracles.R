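# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (dense loops instead of separable /
# FFT / union-find shortcuts).

# Dense 2-D Gaussian convolution with reflected boundary.
oracleGaussBlur <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  g1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  k2 <- outer(g1, g1)
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {
    i <- abs(i - 1L) + 1L
    ifelse(i > n, 2L * n - i, i)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in -r:r) {
        ia <- refl(i + a, nr)
        for (b in -r:r)
          acc <- acc + k2[a + r + 1L, b + r + 1L] * img[ia, refl(j + b, nc)]
      }
      out[i, j] <- acc
    }
  }
  out
}

oracleBandpass <- function(img, kernelPx) {
  oracleGaussBlur(img, kernelPx / 2) - oracleGaussBlur(img, kernelPx)
}

# Exhaustive integer-shift cross-correlation alignment of `frame` to
# `template`; returns the correction offset (dy, dx) to apply to the frame.
oracleAlign <- function(template, frame, maxShift = 6L) {
  best <- c(0L, 0L); bestScore <- -Inf
  t0 <- template - mean(template)
  for (dy in -maxShift:maxShift) {
    for (dx in -maxShift:maxShift) {
      rows <- seq_len(nrow(frame))
      cols <- seq_len(ncol(frame))
      rs <- rows[rows + dy >= 1 & rows + dy <= nrow(frame)]
      cs <- cols[cols + dx >= 1 & cols + dx <= ncol(frame)]
      shifted <- frame[rs, cs, drop = FALSE]
      score <- sum(t0[rs + dy, cs + dx] * (shifted - mean(shifted)))
      if (score > bestScore + 1e-9) { bestScore <- score; best <- c(dy, dx) }
    }
  }
  best
}

# Steepest-ascent climb (8-neighborhood; neighbors scanned in lexicographic
# (row, col) order, strict improvement only, so the first maximal neighbor
# wins ties) from one pixel of image `bp`; returns the linear index of the
# attracting peak.
oracleClimb <- function(bp, i, j) {
  repeat {
    bi <- i; bj <- j; bv <- bp[i, j]
    for (a in -1:1) for (b in -1:1) {
      if (a == 0 && b == 0) next
      ii <- i + a; jj <- j + b
      if (ii < 1 || ii > nrow(bp) || jj < 1 || jj > ncol(bp)) next
      if (bp[ii, jj] > bv) { bv <- bp[ii, jj]; bi <- ii; bj <- jj }
    }
    if (bi == i && bj == j) return((j - 1L) * nrow(bp) + i)
    i <- bi; j <- bj
  }
}

# Maximal runs of a logical vector as a two-column matrix (start, end).
oracleRuns <- function(flag) {
  idx <- which(flag)
  if (!length(idx)) return(matrix(integer(), 0, 2))
  brk <- which(diff(idx) > 1L)
  cbind(idx[c(1L, brk + 1L)], idx[c(brk, length(idx))])
}

# Planted-vs-detected matching: TRUE for each truth row that overlaps some
# detected event whose halfwidth is within relTol of the true one.
matchRecovered <- function(truth, events, relTol = 0.25) {
  vapply(seq_len(nrow(truth)), function(i) {
    ov <- events$t0_s < truth$t_end_s[i] & events$t_end_s > truth$t0_s[i]
    any(ov & abs(events$halfwidth_s - truth$halfwidth_s[i]) <=
          relTol * truth$halfwidth_s[i])
  }, logical(1))
}
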