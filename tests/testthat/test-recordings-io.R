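test_that("write/read round trip is lossless for values and masks", {
  dir <- withr::local_tempdir()
  params <- simulationParams(nSubjects = 2L, dropoutRate = 0.005, seed = 3L)
  rec <- simulateRecording(params, 1L, "fatigued")[["TAL"]]
  expect_gt(sum(rec@emgMask), 0L)  # dropout actually injected
  imu <- file.path(dir, "imu.csv"); emg <- file.path(dir, "emg.csv")
  writeRecording(rec, imu, emg)
  back <- readRecording(imu, emg, rec@subjectId, rec@state, rec@site)
  expect_identical(back@accMask, rec@accMask)
  expect_identical(back@gyroMask, rec@gyroMask)
  expect_identical(back@emgMask, rec@emgMask)
  expect_identical(back@acc[!rec@accMask], rec@acc[!rec@accMask])
  expect_identical(back@gyro[!rec@gyroMask], rec@gyro[!rec@gyroMask])
  expect_identical(back@emg[!rec@emgMask], rec@emg[!rec@emgMask])
})

test_that("recordings with unmasked non-finite values are refused on write", {
  params <- simulationParams(nSubjects = 2L, seed = 3L)
  rec <- simulateRecording(params, 1L, "non_fatigued")[["GLL"]]
  rec@emg[10L] <- NaN  # bypasses the constructor's validity check
  dir <- withr::local_tempdir()
  expect_error(writeRecording(rec, file.path(dir, "i.csv"),
                              file.path(dir, "e.csv")),
               "mask")
})

test_that("malformed signal files are rejected with informative errors", {
  dir <- withr::local_tempdir()
  # IMU file with one extra data column
  bad <- file.path(dir, "bad_imu.csv")
  writeLines(c("time,ax,ay,az,gx,gy,gz,extra",
               "0,1,1,1,1,1,1,1"), bad)
  okEmg <- file.path(dir, "e.csv")
  writeLines(c("time,emg", "0,0.1"), okEmg)
  expect_error(readRecording(bad, okEmg, "S01", "fatigued", "TAL"),
               "format error")
  # rate mismatch between time column and declared rate
  slow <- file.path(dir, "slow_imu.csv")
  writeLines(c("time,ax,ay,az,gx,gy,gz",
               paste(sprintf("%g", (0:147) / 74), "0,0,0,0,0,0",
                     sep = ",")), slow)
  okEmg2 <- file.path(dir, "e2.csv")
  writeLines(c("time,emg",
               paste(sprintf("%g", (0:2517) / 1259), "0", sep = ",")),
             okEmg2)
  expect_error(readRecording(slow, okEmg2, "S01", "fatigued", "TAL"),
               "rate error")
})

test_that("blank cells become masked samples on read", {
  dir <- withr::local_tempdir()
  imu <- file.path(dir, "imu.csv")
  n <- 148L
  rows <- sprintf("%g,0,0,0,0,0,0", (seq_len(n) - 1) / 148)
  rows[5L] <- sprintf("%g,,0,0,0,0,0", 4 / 148)
  writeLines(c("time,ax,ay,az,gx,gy,gz", rows), imu)
  emg <- file.path(dir, "emg.csv")
  writeLines(c("time,emg",
               sprintf("%g,0.1", (0:1258) / 1259)), emg)
  rec <- readRecording(imu, emg, "S01", "non_fatigued", "TAL")
  expect_true(rec@accMask[5L, 1L])
  expect_identical(sum(rec@accMask), 1L)
})

test_that("manifest validation keeps exactly the complete site groups", {
  entries <- manifestEntries(sprintf("S%02d", 1:35))
  expect_identical(nrow(entries), 420L)
  path <- writeManifestJSON(entries)
  man <- readManifest(path)
  expect_identical(nrow(recordingGroups(man)), 70L)

  # property: random site deletions knock out exactly the affected groups
  set.seed(42)
  for (rep in 1:5) {
    ent <- manifestEntries(sprintf("S%02d", 1:6))
    drop <- sample(nrow(ent), sample(1:5, 1))
    broken <- unique(paste(ent$subject[drop], ent$state[drop]))
    ent <- ent[-drop, ]
    man <- suppressWarnings(readManifest(writeManifestJSON(ent)))
    kept <- with(recordingGroups(man), paste(subject, state))
    full <- manifestEntries(sprintf("S%02d", 1:6))
    allGroups <- unique(paste(full$subject, full$state))
    expect_setequal(kept, setdiff(allGroups, broken))
  }
})

test_that("duplicate manifest triples and empty manifests are errors", {
  entries <- manifestEntries("S01")
  dup <- rbind(entries, entries[1L, ])
  expect_error(readManifest(writeManifestJSON(dup)), "duplicate")
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "manifest.json")
  file.create(empty)
  expect_error(readManifest(empty), "manifest error")
})
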