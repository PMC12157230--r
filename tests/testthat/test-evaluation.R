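randomSegments <- function(nSubjects, windows = 3L, frames = 24L,
                           channels = 2L, seed = 1L) {
  set.seed(seed)
  n <- nSubjects * 2L * windows
  methods::new("SegmentSet",
    data = array(rnorm(n * frames * channels), c(n, frames, channels)),
    labels = rep(rep(c(0L, 1L), each = windows), nSubjects),
    subjects = rep(sprintf("S%02d", seq_len(nSubjects)), each = 2L * windows),
    channelNames = paste0("ch", seq_len(channels)),
    windowFrames = frames, hopFrames = frames %/% 2L)
}

test_that("LOSOCV folds are subject-pure, disjoint and covering", {
  for (nSubj in c(2L, 5L, 9L)) {
    segs <- randomSegments(nSubj, seed = nSubj)
    folds <- losocvSplit(segs)
    expect_length(folds, nSubj)
    allTest <- sort(unlist(lapply(folds, `[[`, "test")))
    expect_identical(allTest, seq_len(nSegments(segs)))  # coverage, once
    subj <- segmentSubjects(segs)
    for (f in folds) {
      expect_length(intersect(f$train, f$test), 0L)
      expect_identical(unique(subj[f$test]), f$subject)   # purity
      expect_false(f$subject %in% subj[f$train])
      expect_identical(sort(c(f$train, f$test)), seq_len(nSegments(segs)))
    }
  }
  # a 35-subject cohort would give 35 folds of 18 test segments each
  segs35 <- randomSegments(35L, windows = 9L, frames = 8L, channels = 1L)
  folds <- losocvSplit(segs35)
  expect_length(folds, 35L)
  expect_true(all(vapply(folds, function(f) length(f$test), integer(1)) == 18L))
})

test_that("kfold9 folds hold out one window index per subject-state", {
  segs <- randomSegments(5L, windows = 9L, seed = 3L)
  folds <- kfold9Split(segs)
  expect_length(folds, 9L)
  y <- segmentLabels(segs)
  for (f in folds) {
    expect_length(f$test, 5L * 2L)                   # 2 x n_subjects
    expect_identical(sum(y[f$test] == 0L), 5L)       # exact label balance
    expect_identical(sum(y[f$test] == 1L), 5L)
    expect_length(intersect(f$train, f$test), 0L)
  }
  allTest <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(allTest, seq_len(nSegments(segs)))  # partition
  # ragged window counts are refused
  expect_error(kfold9Split(subsetSegments(segs, -1L)), "exactly 9")
})

test_that("fold membership does not depend on segment order", {
  segs <- randomSegments(4L, seed = 9L)
  perm <- sample(nSegments(segs))
  shuffled <- subsetSegments(segs, perm)
  f1 <- losocvSplit(segs)
  f2 <- losocvSplit(shuffled)
  key <- function(segs, folds) lapply(folds, function(f)
    sort(paste(segmentSubjects(segs)[f$test], segmentLabels(segs)[f$test])))
  expect_identical(key(segs, f1), key(shuffled, f2))
})

test_that("metrics match a brute-force recount of random prediction pairs", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    truth <- rbinom(n, 1L, 0.5)
    pred <- ifelse(runif(n) < 0.7, truth, 1L - truth)
    cc <- confusionCounts(pred, truth)
    expect_equal(unname(sum(cc)), n)
    m <- computeMetrics(cc)
    expect_equal(m$accuracy, mean(pred == truth))
    if (any(pred == 1L))
      expect_equal(m$precision, mean(truth[pred == 1L] == 1L))
    if (any(truth == 1L))
      expect_equal(m$recall, mean(pred[truth == 1L] == 1L))
    if (any(truth == 0L))
      expect_equal(m$recallNegative, mean(pred[truth == 0L] == 0L))
  }
})

test_that("degenerate confusion tables follow the documented 0-with-flag rule", {
  perfect <- computeMetrics(c(TP = 1, FP = 0, TN = 1, FN = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_false(perfect$degenerate)
  never <- computeMetrics(c(TP = 0, FP = 0, TN = 5, FN = 5))
  expect_equal(never$recall, 0)
  expect_equal(never$precision, 0)
  expect_true(never$degenerate)
  expect_error(computeMetrics(c(TP = -1, FP = 0, TN = 1, FN = 0)),
               "negative")
})

test_that("published per-class recalls reconstruct the published accuracies", {
  # 315 segments per class; counts recovered from the printed recalls
  reconstruct <- function(recallF, recallNF, perClass = 315L) {
    TP <- round(recallF * perClass); TN <- round(recallNF * perClass)
    c(TP = TP, FP = perClass - TN, TN = TN, FN = perClass - TP)
  }
  cc3 <- reconstruct(0.8476, 0.9111)
  m3 <- computeMetrics(cc3)
  expect_identical(round(m3$accuracy, 4), 0.8794)
  expect_identical(round(m3$precision, 4), 0.9051)
  expect_identical(round(m3$precisionNegative, 4), 0.8567)
  cc13 <- reconstruct(0.8794, 0.8603)
  m13 <- computeMetrics(cc13)
  expect_identical(round(m13$accuracy, 4), 0.8698)
  expect_identical(round(m13$precision, 4), 0.8629)
  expect_identical(round(m13$precisionNegative, 4), 0.8770)
})

test_that("runCV pools fold counts consistently and renders its artifacts", {
  segs <- smallCohortSegments()
  rep <- runCV(segs, 3, "losocv",
               cfg = smallModelConfig(maxEpochs = 4L, patience = 2L),
               seed = 71L)
  expect_identical(length(rep@folds), 4L)
  expect_identical(Reduce(`+`, lapply(rep@folds, `[[`, "counts")),
                   rep@pooled)
  expect_equal(unname(sum(rep@pooled)), 72)
  expect_identical(nrow(rep@perSubject), 4L)
  expect_true(all(rep@perSubject$nSegments == 18L))
  expect_true(all(names(rep@attention) %in% fatigueStates()))

  dir <- withr::local_tempdir()
  paths <- renderReports(rep, dir)
  expect_true(file.exists(file.path(dir, "metrics.json")))
  js <- jsonlite::read_json(file.path(dir, "metrics.json"),
                            simplifyVector = TRUE)
  expect_equal(js$pooled_metrics$accuracy, pooledAccuracy(rep))
  expect_identical(sum(unlist(js$pooled_counts)), 72L)
  cm <- as.matrix(utils::read.csv(file.path(dir, "confusion.csv"),
                                  row.names = 1))
  expect_equal(unname(sum(cm)), 72)
  # re-rendering is byte-identical
  dir2 <- withr::local_tempdir()
  renderReports(rep, dir2)
  expect_identical(readLines(file.path(dir, "metrics.json")),
                   readLines(file.path(dir2, "metrics.json")))
})
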