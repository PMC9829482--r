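test_that("fixed seeds give bit-identical simulations without touching the RNG", {
  ev <- data.frame(t0_s = 10, halfwidth_s = 3, z_max = 8)
  a <- simulateTrace(30, events = ev, seed = 7)
  b <- simulateTrace(30, events = ev, seed = 7)
  expect_identical(a$x, b$x)
  expect_false(identical(a$x, simulateTrace(30, events = ev, seed = 8)$x))

  # the generator must not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(simulateTrace(5, seed = 99)); r2 <- runif(1)
  expect_identical(r1, r2)

  cfg <- simConfig(fovPx = c(32L, 32L), nCells = 2, duration = 2, seed = 5)
  m1 <- simulateMovie(cfg)
  m2 <- simulateMovie(cfg)
  expect_identical(movieData(m1$movie), movieData(m2$movie))
  expect_identical(m1$truth$events, m2$truth$events)
})

test_that("pure background is Poisson with the configured baseline", {
  sim <- simulateTrace(500, baseline = 100, events = NULL, seed = 17)
  expect_equal(mean(sim$x), 100, tolerance = 0.01)
  expect_equal(var(sim$x) / mean(sim$x), 1, tolerance = 0.05)
  expect_true(all(sim$lambda == 100))

  z <- zScore(zscoreTrace(sim$x, sim$frameRate, fCut = 0.05))
  expect_equal(mean(abs(z) < 2), 0.9545, tolerance = 0.01)
})

test_that("per-pixel variance/mean slope matches the configured gain", {
  sim <- simulateMovie(simConfig(fovPx = c(48L, 48L), nCells = 3,
                                 duration = 10, events = "none", seed = 29))
  d <- movieData(sim$movie)
  flat <- matrix(d, nrow = dim(d)[1])
  m <- colMeans(flat)
  v <- apply(flat, 2, var)
  slope <- coef(lm(v ~ m - 1))[[1]]            # independent regression oracle
  expect_equal(slope, 1, tolerance = 0.05)
  expect_equal(calibrateGain(sim$movie), 1, tolerance = 0.05)

  g2 <- simulateMovie(simConfig(fovPx = c(48L, 48L), nCells = 3,
                                duration = 10, events = "none", gain = 2,
                                seed = 29))
  expect_equal(calibrateGain(g2$movie), 2, tolerance = 0.1)
})

test_that("planted waveforms have the requested halfwidth and class", {
  for (hw in c(0.5, 3, 20)) {
    sim <- simulateTrace(150, events = data.frame(t0_s = 70, halfwidth_s = hw,
                                                  z_max = 8), seed = 31)
    expect_equal(sim$truth$halfwidth_s, hw, tolerance = 0.1)
    expect_equal(sim$truth$class,
                 as.character(cut(hw, c(0, 2, 8.5, Inf),
                                  c("ultra_short", "short", "long"),
                                  right = FALSE)))
    # the noiseless intensity really peaks near z_max * sqrt(baseline)
    expect_equal(max(sim$lambda) - 100, 8 * sqrt(100), tolerance = 0.5)
  }
  # requested ultra-short events cannot be narrower than the unitary kernel
  uni <- simulateTrace(30, events = data.frame(t0_s = 10, halfwidth_s = 0.05,
                                               z_max = 8), seed = 32)
  expect_lt(uni$truth$halfwidth_s, 0.5)
})

test_that("a planted rectangular-like event yields a candidate within 20%", {
  sim <- simulateTrace(120, events = data.frame(t0_s = 60, halfwidth_s = 5,
                                                z_max = 8), seed = 37)
  zs <- zscoreTrace(sim$x, sim$frameRate, fCut = 1 / 32)
  cand <- detectCandidates(zs)
  hit <- which(cand$t0_s < sim$truth$t_end_s & cand$t_end_s > sim$truth$t0_s)
  expect_gte(length(hit), 1)
  best <- hit[which.min(abs(cand$halfwidth_s[hit] - sim$truth$halfwidth_s))]
  expect_equal(cand$halfwidth_s[best], sim$truth$halfwidth_s, tolerance = 0.2)
})

test_that("movie events land on the planted cells with the planted timing", {
  plan <- data.frame(cell = c(1L, 2L), t0_s = c(8, 15),
                     halfwidth_s = c(2, 4), z_max = c(9, 9))
  sim <- simulateMovie(simConfig(fovPx = c(64L, 64L), nCells = 2,
                                 duration = 30, events = plan, seed = 43))
  expect_equal(nrow(sim$truth$events), 2)
  expect_equal(sim$truth$events$halfwidth_s, plan$halfwidth_s,
               tolerance = 0.1)
  # the summed trace over the planted cell shows the event at z ~ 9
  cells <- sim$truth$cells
  d <- movieData(sim$movie)
  for (i in 1:2) {
    dd <- sqrt(outer((1:64 - cells$row[i])^2, (1:64 - cells$col[i])^2, `+`))
    x <- rowSums(matrix(d, nrow = dim(d)[1])[, which(dd <= cells$radius_px)])
    zs <- zscoreTrace(x, 20, fCut = 1 / 16)
    expect_gt(max(zScore(zs)), 6)
    pk <- (which.max(zScore(zs)) - 1) / 20
    expect_lt(abs(pk - (plan$t0_s[i] + plan$halfwidth_s[i] / 2)),
              plan$halfwidth_s[i] * 1.5)
  }
})

test_that("infeasible geometries are rejected", {
  expect_error(simConfig(fovPx = c(8L, 8L)), "geometry")
  expect_error(simulateMovie(simConfig(fovPx = c(40L, 40L), nCells = 12,
                                       duration = 1, seed = 3)), "geometry")
})

test_that("planted drift is recorded and recoverable by motion correction", {
  drift <- data.frame(frame = 1:60, dy = c(rep(0L, 44), rep(4L, 16)), dx = 0L)
  sim <- simulateMovie(simConfig(fovPx = c(48L, 48L), nCells = 2, duration = 3,
                                 events = "none", cellBrightness = 30,
                                 drift = drift, seed = 47))
  off <- estimateMotion(sim$movie, workRate = 10)
  expect_equal(median(off$dy[47:60]), -4)
  expect_equal(median(off$dy[1:44]), 0)
})
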