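test_that("TIFF round trip preserves counts and metadata validation works", {
  arr <- array(3, c(10, 8, 8))
  mov <- CaMovie(arr, frameRate = 20, pixelSize = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  writeMovie(mov, path)
  back <- loadMovie(path, frameRate = 20, pixelSize = 1)
  expect_equal(dim(back), c(10, 8, 8))
  expect_true(all(movieData(back) == 3))
  expect_equal(frameRate(back), 20)

  # a single-page image is not a movie
  single <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), single)
  expect_error(loadMovie(single, 20, 1), "multipage")
  expect_error(loadMovie("no/such/file.tif", 20, 1), "read")

  # class invariants
  expect_error(CaMovie(array(-1, c(2, 2, 2)), 20, 1), "non-negative")
  expect_error(CaMovie(array(1, c(2, 2, 2)), -20, 1), "positive")
  expect_error(CaMovie(matrix(1, 2, 2), 20, 1))
})

test_that("frame statistics match brute-force per-pixel computation", {
  set.seed(101)
  arr <- array(rpois(20 * 5 * 5, 7), c(20, 5, 5))
  mov <- CaMovie(arr, frameRate = 20, pixelSize = 1)

  expect_equal(frameStatistic(mov, "mean"), apply(arr, c(2, 3), mean))
  expect_equal(frameStatistic(mov, "std"), apply(arr, c(2, 3), sd))
  d1 <- arr[-1, , ] - arr[-20, , ]
  expect_equal(frameStatistic(mov, "diff_mean"), apply(d1, c(2, 3), mean))
  expect_equal(frameStatistic(mov, "diff_std"), apply(d1, c(2, 3), sd))
  expect_equal(frameStatistic(mov, "robust_max", robustRank = 3),
               apply(abs(arr), c(2, 3), function(v) sort(v, decreasing = TRUE)[3]))

  # constant movie
  cm <- CaMovie(array(5, c(12, 3, 3)), 20, 1)
  expect_true(all(frameStatistic(cm, "mean") == 5))
  expect_true(all(frameStatistic(cm, "std") == 0))
})

test_that("robust maximum is an order statistic, insensitive to one outlier", {
  x <- c(rep(10, 99), 1000)
  arr <- array(0, c(100, 2, 2))
  arr[, 1, 1] <- x
  arr[, 2, 2] <- sample(x)        # permuted frames
  mov <- CaMovie(arr, 20, 1)
  rm10 <- frameStatistic(mov, "robust_max", robustRank = 10)
  expect_equal(rm10[1, 1], 10)    # the 10th largest ignores the spike
  expect_equal(rm10[2, 2], rm10[1, 1])  # frame-permutation invariance
  expect_error(frameStatistic(CaMovie(array(1, c(5, 2, 2)), 20, 1),
                              "robust_max", robustRank = 10), "robustRank")

  # representative = mean of mean image and robust-max image
  arr2 <- array(0, c(100, 1, 1))
  arr2[, 1, 1] <- c(rep(8, 50), rep(0, 50))  # mean 4, 10th largest 8
  rep4 <- frameStatistic(CaMovie(arr2, 20, 1), "representative")
  expect_equal(rep4[1, 1], 6)
})

test_that("temporal rebinning combines frames and rescales the rate", {
  expect_equal(rebinTime(c(1, 2, 3, 4), 2, "sum"), c(3, 7))
  expect_equal(rebinTime(c(1, 2, 3, 4), 2, "mean"), c(1.5, 3.5))
  expect_identical(rebinTime(c(1, 2, 3), 1), c(1, 2, 3))
  expect_error(rebinTime(c(1, 2), 0), "factor")
  expect_message(rebinTime(c(1, 2, 3, 4, 5), 2), "dropping 1")

  set.seed(7)
  arr <- array(rpois(9 * 4 * 4, 6), c(9, 4, 4))
  mov <- CaMovie(arr, 20, 1)
  reb <- suppressMessages(rebinTime(mov, 4, "sum"))
  expect_equal(nFrames(reb), 2)
  expect_equal(frameRate(reb), 5)
  expect_equal(sum(movieData(reb)), sum(arr[1:8, , ]))  # counts conserved
})

test_that("mean-mode rebinning shrinks Poisson noise by sqrt(n)", {
  set.seed(11)
  x <- rpois(1e5, 100)
  r4 <- rebinTime(x, 4, "mean")
  expect_equal(sd(r4), 10 / sqrt(4), tolerance = 0.02)
  # sum mode keeps the Poisson variance = mean relation
  s4 <- rebinTime(x, 4, "sum")
  expect_equal(var(s4) / mean(s4), 1, tolerance = 0.05)
})

test_that("motion estimation recovers planted drift, matching exhaustive search", {
  # one bright disk, shifted by (+3, 0) in the second half
  base <- matrix(0, 32, 32)
  dd <- sqrt(outer((1:32 - 14)^2, (1:32 - 16)^2, `+`))
  base[dd < 5] <- 50
  # 15 stable frames, then 5 shifted: the template (rebinned-movie mean) is
  # dominated by the stable position, so the shifted frames align strictly
  arr <- array(0, c(20, 32, 32))
  for (i in 1:15) arr[i, , ] <- base
  shifted <- rbind(matrix(0, 3, 32), base[1:29, ])
  for (i in 16:20) arr[i, , ] <- shifted
  mov <- CaMovie(arr, frameRate = 20, pixelSize = 1)
  off <- estimateMotion(mov, workRate = 10)
  expect_equal(nrow(off), 20)
  expect_true(all(off$dy[17:20] == -3 & off$dx[17:20] == 0))
  expect_true(all(off$dy[1:14] == 0 & off$dx[1:14] == 0))

  # exhaustive-search oracle on the rebinned frames
  reb <- suppressMessages(rebinTime(mov, 2, "mean"))
  d <- movieData(reb)
  tmpl <- apply(d, c(2, 3), mean)
  for (i in c(1, 5, 9, 10)) {
    expect_equal(unname(unlist(off[2 * i, c("dy", "dx")])),
                 oracleAlign(tmpl, d[i, , ]))
  }

  expect_warning(estimateMotion(CaMovie(array(2, c(10, 16, 16)), 20, 1)),
                 "flat")
})

test_that("pure-noise movies yield only small spurious offsets", {
  set.seed(5)
  mov <- CaMovie(array(rpois(40 * 24 * 24, 30), c(40, 24, 24)), 20, 1)
  off <- estimateMotion(mov, workRate = 5)
  expect_lte(mean(abs(off$dy)), 1)
  expect_lte(mean(abs(off$dx)), 1)
})

test_that("applyMotion shifts frames, zero-fills, and round-trips interiors", {
  set.seed(3)
  arr <- array(rpois(4 * 10 * 10, 20), c(4, 10, 10))
  mov <- CaMovie(arr, 20, 1)
  zero <- data.frame(frame = 1:4, dy = 0, dx = 0)
  expect_equal(movieData(applyMotion(mov, zero)), arr)

  fwd <- data.frame(frame = 1:4, dy = 2, dx = -1)
  bwd <- data.frame(frame = 1:4, dy = -2, dx = 1)
  rt <- applyMotion(applyMotion(mov, fwd), bwd)
  expect_equal(movieData(rt)[, 3:8, 2:9], arr[, 3:8, 2:9])
  expect_error(applyMotion(mov, zero[1:2, ]), "one row per frame")
})

test_that("correcting a planted drift reduces edge variance", {
  base <- matrix(2, 24, 24)
  dd <- sqrt(outer((1:24 - 12)^2, (1:24 - 12)^2, `+`))
  base[dd < 5] <- 40
  arr <- array(0, c(30, 24, 24))
  set.seed(9)
  for (i in 1:30) {
    dy <- if (i > 15) 3L else 0L
    arr[i, , ] <- rpois(576, ifelse(dd < 5, 40, 2))
    if (dy != 0) arr[i, , ] <- rbind(matrix(2, dy, 24), arr[i, 1:(24 - dy), ])
  }
  mov <- CaMovie(arr, frameRate = 10, pixelSize = 1)
  off <- estimateMotion(mov, workRate = 5)
  cor <- applyMotion(mov, off)
  edge <- which(abs(dd - 5) < 1.5)
  sdOf <- function(m) mean(apply(matrix(movieData(m), 30)[, edge], 2, sd))
  expect_lt(sdOf(cor), sdOf(mov))
})
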