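test_that("outlier masking follows the single-pass k-SD rule", {
  x <- c(rep(0, 99), 10)          # mean 0.1, SD exactly 1 -> z(10) = 9.9
  r <- removeOutliers(x, mask = rep(FALSE, 100L), k = 3)
  expect_identical(which(r$mask), 100L)
  expect_identical(r$x, x)        # values untouched

  const <- rep(5, 50)
  r <- removeOutliers(const, rep(FALSE, 50L))
  expect_false(any(r$mask))       # SD = 0: nothing exceeds

  expect_error(removeOutliers(c(1, 2), mask = c(TRUE, TRUE)), "masked")
})

test_that("on a large standard-normal sample ~0.27% of samples are masked", {
  set.seed(123)
  x <- rnorm(1e6)
  r <- removeOutliers(x, rep(FALSE, length(x)))
  frac <- mean(r$mask)
  expect_lt(abs(frac - 2 * pnorm(-3)), 3e-4)
})

test_that("gap interpolation is linear inside, nearest at edges, idempotent", {
  expect_equal(interpolateMissing(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(interpolateMissing(c(NA, 5, 5, NA)), c(5, 5, 5, 5))
  # linear data are recovered exactly however interior points are masked
  set.seed(9)
  for (rep in 1:5) {
    ramp <- seq(0, 10, length.out = 50)
    x <- ramp
    holes <- sample(2:49, 3)
    x[holes] <- NA
    expect_equal(interpolateMissing(x), ramp, tolerance = 1e-12)
  }
  y <- interpolateMissing(c(1, NA, 3, NA, NA, 7))
  expect_identical(interpolateMissing(y, rep(FALSE, length(y))), y)
  expect_error(interpolateMissing(rep(NA_real_, 4)), "fully masked")
})

test_that("band-pass passes mid-band, rejects DC and 2x the high edge", {
  fs <- 148
  t <- seq(0, 12, by = 1 / fs)
  mid <- seq(300L, length(t) - 300L)  # steady-state region
  y10 <- bandpassFilter(sin(2 * pi * 10 * t), c(1, 20), fs)
  amp10 <- max(abs(y10[mid]))
  expect_gte(amp10, 0.95); expect_lte(amp10, 1.0)
  y40 <- bandpassFilter(sin(2 * pi * 40 * t), c(1, 20), fs)
  expect_lt(max(abs(y40[mid])), 0.1)               # >= 20 dB down
  ydc <- bandpassFilter(rep(1, length(t)), c(1, 20), fs)
  expect_lt(max(abs(ydc[mid])), 0.1)               # >= 20 dB down
  # analytic DC rejection: the designed transfer function is exactly 0 at z=1
  bf <- signal::butter(4, c(1, 20) / (fs / 2), type = "pass")
  expect_lt(abs(sum(bf$b) / sum(bf$a)), 1e-6)
  expect_error(bandpassFilter(t, c(20, 500), fs), "Nyquist")
})

test_that("rectification and smoothing behave as envelope primitives", {
  expect_identical(rectifyEMG(c(-1, 2, -3)), c(1, 2, 3))
  x <- abs(rnorm(10))
  expect_identical(rectifyEMG(rectifyEMG(x)), rectifyEMG(x))

  expect_equal(movingAverage(rep(4, 100), fs = 148), rep(4, 100))
  # unit impulse at fs=148: window = round(14.8) = 15 samples -> plateau 1/15
  imp <- rep(0, 200); imp[100L] <- 1
  sm <- movingAverage(imp, fs = 148)
  expect_equal(sum(sm > 0), 15L)
  expect_equal(unique(round(sm[sm > 0], 12)), round(1 / 15, 12))
  # interior of a ramp is invariant under a symmetric mean
  ramp <- seq_len(100)
  expect_equal(movingAverage(ramp, fs = 148)[20:80], ramp[20:80])
  expect_error(movingAverage(1:5, fs = 148), "window")
})

test_that("jerk equals the closed-form forward difference on polynomials", {
  # degree <= 1: exact constant slope, last frame replicated
  a <- cbind(0:3, 2 * (0:3), rep(1, 4))
  expect_equal(linearJerk(a, fs = 1), cbind(rep(1, 4), rep(2, 4), rep(0, 4)))
  # degree 2 at fs = 100: (t+dt)^2 - t^2)/dt = 2t + dt exactly
  fs <- 100; t <- (0:499) / fs
  j <- linearJerk(cbind(t^2, t^2, t^2), fs)
  expected <- 2 * t + 1 / fs
  expected[length(t)] <- expected[length(t) - 1L]
  expect_lt(max(abs(j[, 1] - expected)), 1e-9)
  # angular jerk: same operator; sinusoid matches derivative to O(dt)
  fs <- 148; t <- (0:499) / fs
  w <- cbind(sin(2 * pi * 2 * t), 0, 0)
  aj <- angularJerk(w, fs)
  analytic <- 2 * pi * 2 * cos(2 * pi * 2 * t)
  bound <- 0.5 * (2 * pi * 2)^2 / fs  # |x''|max * dt / 2
  expect_lt(max(abs(aj[-500, 1] - analytic[-500])), bound * 1.01)
  # second-derivative option reduces a linear ramp to zero
  expect_equal(unname(angularJerk(cbind(t, t, t), fs, order = 2L)[10, 1]), 0)
  expect_error(linearJerk(matrix(1, 1, 3), 148), "2 frames")
})

test_that("resampling preserves length arithmetic and in-band amplitude", {
  x <- rnorm(100)
  expect_identical(resampleSignal(x, 148, 148), x)
  emg <- rnorm(18900)
  expect_equal(length(resampleSignal(emg, 1259, 148)),
               round(18900 * 148 / 1259))
  t <- (0:18899) / 1259
  s5 <- sin(2 * pi * 5 * t)
  r <- resampleSignal(s5, 1259, 148)
  mid <- seq(200L, length(r) - 200L)
  expect_lt(abs(max(abs(r[mid])) - 1), 0.01)
  expect_error(resampleSignal(x, -1, 148), "positive")
})

test_that("a clean 15 s group yields 2220 aligned frames with 42 channels", {
  params <- simulationParams(nSubjects = 2L, durationS = 15, seed = 21L)
  group <- simulateRecording(params, 1L, "non_fatigued")
  pr <- preprocessRecording(group)
  expect_identical(nrow(pr@data), 2220L)
  expect_identical(ncol(pr@data), 42L)
  expect_true(all(is.finite(pr@data)))
  expect_identical(pr@channelNames[1:3], c("TAL.emg", "TAL.linjerk.x",
                                           "TAL.linjerk.y"))
  # determinism: reprocessing the same input gives identical output
  pr2 <- preprocessRecording(group)
  expect_identical(pr@data, pr2@data)
})

test_that("dropout-afflicted recordings come out gap-free and same shape", {
  clean <- simulationParams(nSubjects = 2L, seed = 31L)
  noisy <- simulationParams(nSubjects = 2L, dropoutRate = 0.01, seed = 31L)
  prC <- preprocessRecording(simulateRecording(clean, 1L, "fatigued"))
  prN <- preprocessRecording(simulateRecording(noisy, 1L, "fatigued"))
  expect_identical(dim(prC@data), dim(prN@data))
  expect_true(all(is.finite(prN@data)))
})

test_that("incomplete site groups are rejected", {
  params <- simulationParams(nSubjects = 2L, seed = 41L)
  group <- simulateRecording(params, 1L, "non_fatigued")
  expect_error(preprocessRecording(group[-2L]), "missing.*TAR")
})
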