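test_that("simulated recordings have the declared multi-rate geometry", {
  params <- simulationParams(nSubjects = 2L, seed = 51L)
  group <- simulateRecording(params, 1L, "non_fatigued")
  expect_named(group, sensorSites())
  rec <- group[["RFL"]]
  expect_identical(nrow(rec@acc), 2368L)   # 16 s x 148 Hz
  expect_identical(length(rec@emg), 20144L)  # 16 s x 1259 Hz
  expect_true(methods::validObject(rec))
})

test_that("the cohort is a pure function of the master seed", {
  params <- simulationParams(nSubjects = 2L, seed = 52L)
  g1 <- simulateRecording(params, 2L, "fatigued")
  g2 <- simulateRecording(params, 2L, "fatigued")
  expect_identical(g1, g2)
  # on-disk determinism, byte for byte
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateCohort(params, d1)
  simulateCohort(params, d2)
  for (f in list.files(d1)) {
    if (f == "manifest.json") next  # embeds no signal data; root path differs
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a written cohort round-trips through the manifest reader
  man <- readManifest(file.path(d1, "manifest.json"))
  expect_identical(nrow(recordingGroups(man)), 4L)
  back <- readRecordingGroup(man, "S02", "fatigued")
  expect_equal(back[["TAL"]]@acc, g1[["TAL"]]@acc)
})

test_that("subject streams are independent of cohort size", {
  small <- simulationParams(nSubjects = 2L, seed = 53L)
  large <- simulationParams(nSubjects = 4L, seed = 53L)
  expect_identical(simulateRecording(small, 2L, "non_fatigued"),
                   simulateRecording(large, 2L, "non_fatigued"))
})

test_that("fatigue raises jerk, EMG amplitude and left-dominant asymmetry", {
  params <- simulationParams(nSubjects = 3L, seed = 54L)
  for (s in 1:3) {
    nf <- simulateRecording(params, s, "non_fatigued")
    ft <- simulateRecording(params, s, "fatigued")
    jerkRms <- function(g) sqrt(mean(unlist(lapply(
      c("TAL", "TAR"), function(site) (diff(g[[site]]@acc[, 1]) * 148)^2))))
    expect_gt(jerkRms(ft), jerkRms(nf))
  }
  er <- effectReport(params)
  expect_true(all(er$jerkRatio > 1.1))
  expect_true(all(er$emgRatio > 1.1))
  expect_true(all(er$asymmetryFatigued > er$asymmetryNonFatigued))
})

test_that("realized effect ratios track the configured gains", {
  # isolate the jerk gain at low noise: ratio must sit near 1.3
  pj <- simulationParams(nSubjects = 3L, jerkGain = 1.3, emgGain = 1,
                         asymmetryGain = 1, cadenceFactor = 1,
                         accNoiseSd = 0.02, gyroNoiseSd = 0.01, seed = 55L)
  er <- effectReport(pj)
  expect_true(all(er$jerkRatio >= 1.25 & er$jerkRatio <= 1.35))
  expect_true(all(abs(er$emgRatio - 1) < 0.05))
  # null cohort: all ratios ~ 1
  p0 <- simulationParams(nSubjects = 3L, jerkGain = 1, emgGain = 1,
                         asymmetryGain = 1, cadenceFactor = 1, seed = 55L)
  er0 <- effectReport(p0)
  expect_true(all(abs(er0$jerkRatio - 1) < 0.05))
  expect_true(all(abs(er0$emgRatio - 1) < 0.05))
  expect_true(all(abs(er0$asymmetryFatigued - er0$asymmetryNonFatigued) <
                    0.05))
})

test_that("left and right EMG envelopes match up to phase under symmetry", {
  params <- simulationParams(nSubjects = 2L, subjectAmpSd = 0,
                             asymmetryGain = 1, seed = 56L)
  # remove the per-site burst-phase jitter by comparing envelope RMS, which
  # is phase-invariant
  g <- simulateRecording(params, 1L, "fatigued")
  env <- function(site) sqrt(mean(movingAverage(abs(g[[site]]@emg),
                                                fs = 1259)^2))
  expect_equal(env("GLL"), env("GLR"), tolerance = 0.03)
})

test_that("synthetic EMG energy stays essentially inside the 20-500 Hz band", {
  params <- simulationParams(nSubjects = 2L, seed = 57L)
  g <- simulateRecording(params, 1L, "non_fatigued")
  e <- g[["GLL"]]@emg
  filtered <- bandpassFilter(e, c(20, 500), 1259)
  loss <- 1 - sum(filtered^2) / sum(e^2)
  expect_lt(loss, 0.1)
})

test_that("parameter validation guards the simulation envelope", {
  expect_error(simulationParams(nSubjects = 1L), "nSubjects")
  expect_error(simulationParams(durationS = 10), "15 s")
  expect_error(simulationParams(jerkGain = 0), "multipliers")
  expect_error(simulationParams(dropoutRate = 0.5), "dropoutRate")
})
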