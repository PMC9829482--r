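test_that("the timescale ladder starts at 0.5 s with ratio 2^(1/4)", {
  lad <- timescaleLadder(tauMax = 128)
  expect_equal(lad[1], 0.5)
  expect_equal(lad[1:5], c(0.5, 0.5 * 2^0.25, 0.5 * 2^0.5, 0.5 * 2^0.75, 1.0),
               tolerance = 1e-12)
  expect_equal(unique(round(diff(log2(lad)), 10)), 0.25)
  expect_equal(max(lad), 128)
  expect_error(timescaleLadder(tauMax = 0.1), "tauMax")
})

test_that("a frame of 150 counts on a slow component of 100 is a candidate", {
  # z = (150 - 100)/sqrt(100) = 5 > 4
  x <- rep(100, 400)
  x[200] <- 150
  zs <- zscoreTrace(x, 20, fCut = 0.2, nIter = 0)
  expect_equal(zScore(zs)[200], 5, tolerance = 0.05)
  cand <- detectCandidates(zs)
  expect_equal(nrow(cand), 1)
  expect_true(cand$t0_s < 199 / 20 && cand$t_end_s > 199 / 20)
})

test_that("flat z produces no candidates", {
  zs <- zscoreTrace(rep(100, 500), 20, fCut = 1)
  expect_equal(nrow(detectCandidates(zs)), 0)
})

test_that("a 3 s plateau on a noisy baseline is measured within 20% at tau = 16 s", {
  # on a Poisson baseline of 100, samples above z = 3 trigger the iterative
  # outlier replacement, which un-drags the slow component and exposes the
  # plateau; the noiseless elevation alone would stay masked below threshold
  fs <- 20
  errs <- vapply(1:5, function(s) {
    sim <- simulateTrace(80, frameRate = fs, baseline = 100,
                         events = data.frame(t0_s = 40, halfwidth_s = 3,
                                             z_max = 5), seed = 1000 + s)
    zs <- zscoreTrace(sim$x, fs, fCut = 1 / 16)
    cand <- detectCandidates(zs)
    hit <- which(cand$t0_s < sim$truth$t_end_s & cand$t_end_s > sim$truth$t0_s)
    expect_gte(length(hit), 1)
    best <- hit[which.min(abs(cand$halfwidth_s[hit] - 3))]
    expect_equal(cand$t0_s[best], sim$truth$t0_s, tolerance = 1)
    abs(cand$halfwidth_s[best] - sim$truth$halfwidth_s) / sim$truth$halfwidth_s
  }, numeric(1))
  expect_lte(median(errs), 0.2)
})

test_that("raising the threshold never increases the candidate count", {
  for (seed in 1:3) {
    sim <- simulateTrace(80, events = data.frame(
      t0_s = c(20, 50), halfwidth_s = c(1, 4), z_max = c(5, 6)), seed = seed)
    zs <- zscoreTrace(sim$x, sim$frameRate, fCut = 1 / 8)
    n4 <- nrow(detectCandidates(zs, zThresh = 4))
    n5 <- nrow(detectCandidates(zs, zThresh = 5))
    n6 <- nrow(detectCandidates(zs, zThresh = 6))
    expect_lte(n5, n4)
    expect_lte(n6, n5)
  }
})

test_that("a multiscale scan sees a 4 s event on at least four rungs", {
  sim <- simulateTrace(120, events = data.frame(t0_s = 60, halfwidth_s = 4,
                                                z_max = 8), seed = 101)
  cand <- multiscaleScan(sim$x, sim$frameRate, timescaleLadder(tauMax = 32))
  tru <- sim$truth
  hit <- cand$t0_s < tru$t_end_s & cand$t_end_s > tru$t0_s &
    abs(cand$halfwidth_s - tru$halfwidth_s) < 0.5 * tru$halfwidth_s
  expect_gte(length(unique(cand$tau_s[hit])), 4)
  expect_error(multiscaleScan(sim$x, sim$frameRate, timescaleLadder(256)),
               "shorter than the recording")
})

test_that("distilling merges cognates by median and applies the scale rule", {
  fourC <- data.frame(
    tau_s = c(4, 4.76, 5.66, 6.73),
    t0_s = c(10.0, 10.1, 9.9, 10.3),
    t_end_s = c(14.0, 14.2, 13.9, 14.1),
    z_max = c(5, 6, 7, 6.5))
  fourC$halfwidth_s <- fourC$t_end_s - fourC$t0_s
  ev <- distillEvents(fourC, frameRate = 20, duration = 60)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t0_s, 10.05)
  expect_equal(ev$t_end_s, 14.05)
  expect_equal(ev$halfwidth_s, 4.0)
  expect_equal(ev$z_max, 7)
  expect_equal(ev$n_scales, 4L)

  # same set minus one candidate: halfwidth > 2 s needs at least four
  expect_equal(nrow(distillEvents(fourC[1:3, ], 20, 60)), 0)

  # a short event must not be unique to a single timescale
  single <- data.frame(tau_s = 1, t0_s = 10, t_end_s = 11, halfwidth_s = 1,
                       z_max = 5)
  expect_equal(nrow(distillEvents(single, 20, 60)), 0)
  two <- rbind(single, data.frame(tau_s = 1.19, t0_s = 10.05, t_end_s = 11.02,
                                  halfwidth_s = 0.97, z_max = 5.5))
  expect_equal(nrow(distillEvents(two, 20, 60)), 1)

  # events shorter than three frame periods are dropped (0.1 s at 20 Hz)
  brief <- data.frame(tau_s = c(0.5, 0.59), t0_s = c(10, 10.01),
                      t_end_s = c(10.1, 10.11), halfwidth_s = 0.1,
                      z_max = c(5, 5))
  expect_equal(nrow(distillEvents(brief, 20, 60)), 0)

  # events within halfwidth/2 of either end are edge artifacts
  early <- data.frame(tau_s = c(2, 2.38), t0_s = c(0.5, 0.55),
                      t_end_s = c(2.5, 2.45), halfwidth_s = c(2.0, 1.9),
                      z_max = c(5, 5))
  expect_equal(nrow(distillEvents(early, 20, 60)), 0)
  shifted <- early
  shifted$t0_s <- shifted$t0_s + 5
  shifted$t_end_s <- shifted$t_end_s + 5
  expect_equal(nrow(distillEvents(shifted, 20, 60)), 1)
  late <- shifted
  late$t0_s <- late$t0_s + 52.5
  late$t_end_s <- late$t_end_s + 52.5
  expect_equal(nrow(distillEvents(late, 20, 60)), 0)
})

test_that("non-cognate candidates stay separate and output is t0-sorted", {
  tmpl <- data.frame(tau_s = c(1, 1.19, 1.41, 1.68), z_max = 5)
  a <- transform(tmpl, t0_s = 30, t_end_s = 33, halfwidth_s = 3)
  b <- transform(tmpl, t0_s = 10, t_end_s = 13.2, halfwidth_s = 3.2)
  ev <- distillEvents(rbind(a, b), 20, 60)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$t0_s, c(10, 30))

  # per-ROI independence: same candidates in two ROIs give two events each
  withRoi <- rbind(cbind(roi = 1L, rbind(a, b)), cbind(roi = 2L, rbind(a, b)))
  evr <- distillEvents(withRoi, 20, 60)
  expect_equal(nrow(evr), 4)
  expect_equal(sort(unique(evr$roi)), c(1L, 2L))
})

test_that("planted events across the duration classes are recovered", {
  fs <- 20
  recovered <- logical(0)
  for (hw in c(0.3, 3, 10)) {
    dur <- max(120, 6 * hw)
    sim <- simulateTrace(dur, frameRate = fs, events = data.frame(
      t0_s = dur / 2, halfwidth_s = hw, z_max = 8), seed = 300 + hw * 10)
    cand <- multiscaleScan(sim$x, fs, timescaleLadder(tauMax = dur / 3))
    ev <- distillEvents(cand, fs, sim$duration)
    recovered <- c(recovered, matchRecovered(sim$truth, ev))
  }
  expect_true(all(recovered))
})

test_that("a train of unitary transients is seen as shorts and as an envelope", {
  fs <- 20
  train <- data.frame(t0_s = 60 + 0.5 * (0:4), halfwidth_s = 0.3, z_max = 14)
  sim <- simulateTrace(150, frameRate = fs, events = train, seed = 404)
  cand <- multiscaleScan(sim$x, fs, timescaleLadder(tauMax = 32))
  ev <- distillEvents(cand, fs, sim$duration)
  span <- c(min(sim$truth$t0_s), max(sim$truth$t_end_s))
  inSpan <- ev$t0_s < span[2] & ev$t_end_s > span[1]
  shorts <- inSpan & ev$halfwidth_s < 1
  envelope <- inSpan & ev$halfwidth_s > 1.5 & ev$halfwidth_s < 5
  expect_gte(sum(shorts), 2)
  expect_gte(sum(envelope), 1)
  # temporal summation: the envelope is at least as long as the parts minus gaps
  expect_gte(max(ev$halfwidth_s[envelope]),
             sum(sim$truth$halfwidth_s) - 4 * 0.2)
})
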