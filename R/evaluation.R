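#' @include AllClasses.R model.R
NULL

# Two protocols:
#  - losocv: one fold per subject; the fold's test set is that subject's
#    segments (both states), training uses everyone else. Subject-independent.
#  - kfold9: fold j tests window index j of every subject in both states,
#    training on the remaining window indices. Subject-dependent; note that
#    50 %-overlapping windows share frames between train and test folds here,
#    which is part of why subject-dependent accuracy runs higher.
# "fatigued" is the positive class throughout.

#' Leave-one-subject-out fold splits
#'
#' One fold per subject: the test set is all and only that subject's
#' segments. Folds are ordered by sorted subject id, so membership does not
#' depend on the ordering of the input.
#'
#' @param segments a \linkS4class{SegmentSet}.
#' @return List of folds, each \code{list(fold, protocol, subject, train,
#'   test)} with disjoint index vectors covering all segments across folds.
#' @export
losocvSplit <- function(segments) {
  subj <- segmentSubjects(segments)
  y <- segmentLabels(segments)
  ids <- sort(unique(subj))
  if (length(ids) < 2L) stop("losocvSplit: need at least 2 subjects")
  for (s in ids)
    if (length(unique(y[subj == s])) < 2L)
      stop("losocvSplit: subject ", s, " lacks one of the two states")
  lapply(seq_along(ids), function(k) {
    test <- which(subj == ids[k])
    list(fold = k, protocol = "losocv", subject = ids[k],
         train = which(subj != ids[k]), test = test)
  })
}

#' Subject-dependent 9-fold splits by window index
#'
#' Requires every subject-state recording to contribute the same number of
#' windows (9 by default); fold j holds out window index j of every subject
#' in both states, so each fold's test set has \code{2 * n_subjects} segments
#' and is exactly label-balanced. Relies on the deterministic
#' (subject, state, window) segment ordering of
#' \code{\link{assembleDataset}}.
#'
#' @param segments a \linkS4class{SegmentSet}.
#' @param nFolds number of window indices per recording (default 9).
#' @return List of folds as in \code{\link{losocvSplit}} (with
#'   \code{subject = NA}).
#' @export
kfold9Split <- function(segments, nFolds = 9L) {
  subj <- segmentSubjects(segments)
  y <- segmentLabels(segments)
  key <- paste(subj, y)
  counts <- table(key)
  if (!all(counts == nFolds))
    stop("kfold9Split: every (subject, state) must contribute exactly ",
         nFolds, " windows")
  # window index within each (subject, state) block
  widx <- stats::ave(seq_along(key), key, FUN = seq_along)
  lapply(seq_len(nFolds), function(j) {
    test <- which(widx == j)
    list(fold = j, protocol = "kfold9", subject = NA_character_,
         train = which(widx != j), test = test)
  })
}

#' Confusion counts from predictions
#'
#' @param pred,truth integer 0/1 vectors (1 = fatigued = positive class).
#' @return Named numeric vector TP, FP, TN, FN.
#' @export
confusionCounts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  c(TP = sum(pred == 1L & truth == 1L),
    FP = sum(pred == 1L & truth == 0L),
    TN = sum(pred == 0L & truth == 0L),
    FN = sum(pred == 0L & truth == 1L))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Standard confusion-matrix metrics with "fatigued" as the positive class:
#' accuracy (TP+TN)/(TP+FP+TN+FN), precision TP/(TP+FP), recall TP/(TP+FN),
#' F1 = 2PR/(P+R). Per-class values for the negative class are obtained by
#' swapping the positive class. Undefined ratios (0/0) return 0 and set
#' \code{degenerate = TRUE}.
#'
#' @param counts named vector with TP, FP, TN, FN (all non-negative).
#' @return List: accuracy, precision, recall, f1 (positive class = fatigued),
#'   precisionNegative, recallNegative, f1Negative, degenerate flag.
#' @export
computeMetrics <- function(counts) {
  need <- c("TP", "FP", "TN", "FN")
  stopifnot(all(need %in% names(counts)))
  counts <- counts[need]
  if (any(counts < 0)) stop("computeMetrics: negative counts")
  total <- sum(counts)
  if (total == 0) stop("computeMetrics: empty confusion table")
  degenerate <- FALSE
  div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; return(0) }
    num / den
  }
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  precision <- div(TP, TP + FP)
  recall <- div(TP, TP + FN)
  f1 <- if (precision + recall == 0) { degenerate <- TRUE; 0 }
        else 2 * precision * recall / (precision + recall)
  precisionN <- div(TN, TN + FN)
  recallN <- div(TN, TN + FP)
  f1N <- if (precisionN + recallN == 0) { degenerate <- TRUE; 0 }
         else 2 * precisionN * recallN / (precisionN + recallN)
  list(accuracy = (TP + TN) / total,
       precision = precision, recall = recall, f1 = f1,
       precisionNegative = precisionN, recallNegative = recallN,
       f1Negative = f1N, degenerate = degenerate)
}

.metricsTable <- function(pooled, foldMetrics) {
  m <- computeMetrics(pooled)
  data.frame(
    scope = c("pooled", "pooled", "macro"),
    state = c("non_fatigued", "fatigued", "overall"),
    precision = c(m$precisionNegative, m$precision, NA),
    recall = c(m$recallNegative, m$recall, NA),
    f1 = c(m$f1Negative, m$f1, NA),
    accuracy = c(NA, m$accuracy, mean(foldMetrics)),
    stringsAsFactors = FALSE)
}

#' Run cross-validated training and evaluation of one combination
#'
#' For each fold a fresh model is built (fold-specific seed
#' \code{seed + fold}) and trained on the training segments of the selected
#' channels; test predictions are pooled into an overall confusion matrix.
#' Reports pooled metrics, per-fold metrics, per-subject accuracy (one value
#' per held-out subject under LOSOCV; aggregated over folds under kfold9),
#' attention maps of one representative test segment per class, and per-fold
#' training histories.
#'
#' @param segments the full \linkS4class{SegmentSet}.
#' @param spec a \linkS4class{CombinationSpec} or combination id.
#' @param protocol \code{"losocv"} or \code{"kfold9"}.
#' @param cfg a \code{\link{modelConfig}}; its seed anchors every fold.
#' @param seed optional override of \code{cfg$seed}.
#' @param keepHistories store per-fold training histories (default TRUE).
#' @return An \linkS4class{EvalReport}.
#' @export
runCV <- function(segments, spec, protocol = c("losocv", "kfold9"),
                  cfg = smallModelConfig(), seed = NULL,
                  keepHistories = TRUE) {
  protocol <- match.arg(protocol)
  if (!methods::is(spec, "CombinationSpec")) spec <- getCombination(spec)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  sel <- selectChannels(segments, spec)
  splits <- if (protocol == "losocv") losocvSplit(sel) else kfold9Split(sel)
  y <- segmentLabels(sel)
  subj <- segmentSubjects(sel)
  predAll <- rep(NA_integer_, nSegments(sel))
  folds <- vector("list", length(splits))
  attnModel <- NULL
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    foldCfg <- cfg
    foldCfg$seed <- cfg$seed + sp$fold
    trainSet <- subsetSegments(sel, sp$train)
    model <- tryCatch({
      m0 <- buildModel(foldCfg, c(sel@windowFrames, length(spec@channels)),
                       channelNames = spec@channels)
      trainModel(m0, trainSet)
    }, error = function(e)
      stop(sprintf("runCV: training failed in fold %d: %s", sp$fold,
                   conditionMessage(e))))
    if (k == 1L) attnModel <- model
    pr <- predictSegments(model, subsetSegments(sel, sp$test))
    predAll[sp$test] <- pr$label
    cc <- confusionCounts(pr$label, y[sp$test])
    folds[[k]] <- list(fold = sp$fold, protocol = protocol,
                       subject = sp$subject, test = sp$test,
                       pred = pr$label, truth = y[sp$test], counts = cc,
                       metrics = computeMetrics(cc),
                       history = if (keepHistories) model@history else NULL)
  }
  pooled <- Reduce(`+`, lapply(folds, `[[`, "counts"))
  foldAcc <- vapply(folds, function(f) f$metrics$accuracy, numeric(1))
  perSubject <- do.call(rbind, lapply(sort(unique(subj)), function(s) {
    i <- which(subj == s)
    data.frame(subject = s, nSegments = length(i),
               accuracy = mean(predAll[i] == y[i]),
               stringsAsFactors = FALSE)
  }))
  # representative attention maps: first test segment of each class in fold 1,
  # through the fold-1 model (which never saw them in training)
  attn <- list()
  t1 <- splits[[1L]]$test
  for (cl in c(0L, 1L)) {
    i <- t1[which(y[t1] == cl)[1L]]
    if (length(i) == 1L && !is.na(i))
      attn[[fatigueStates()[cl + 1L]]] <-
        attentionWeights(attnModel, sel, index = i)
  }
  methods::new("EvalReport", protocol = protocol, combinationId = spec@id,
               folds = folds, pooled = pooled,
               metrics = .metricsTable(pooled, foldAcc),
               perSubject = perSubject, attention = attn,
               seed = as.integer(cfg$seed))
}

#' Pooled accuracy of an evaluation report
#'
#' @param report an \linkS4class{EvalReport}.
#' @return Numeric scalar in [0, 1].
#' @export
pooledAccuracy <- function(report) computeMetrics(report@pooled)$accuracy

#' Write the report artifacts of an evaluation
#'
#' Emits machine-readable artifacts: \code{metrics.json} (pooled confusion
#' counts, pooled and per-fold metrics, seed), \code{confusion.csv} (2x2
#' pooled matrix), \code{per_subject_accuracy.csv} (radial-chart data),
#' \code{history_fold<k>.csv} learning curves, and
#' \code{attention_<state>.csv} heatmap matrices. Re-rendering the same
#' report produces byte-identical numeric files.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
renderReports <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("renderReports: cannot create ", outdir)
  paths <- character(0)
  p <- file.path(outdir, "metrics.json")
  jsonlite::write_json(list(
    protocol = report@protocol, combination = report@combinationId,
    seed = report@seed,
    pooled_counts = as.list(report@pooled),
    pooled_metrics = computeMetrics(report@pooled)[
      c("accuracy", "precision", "recall", "f1",
        "precisionNegative", "recallNegative", "f1Negative")],
    fold_accuracy = vapply(report@folds, function(f) f$metrics$accuracy,
                           numeric(1))
  ), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  cm <- matrix(report@pooled[c("TN", "FP", "FN", "TP")], 2L, 2L,
               dimnames = list(predicted = fatigueStates(),
                               truth = fatigueStates()))
  p <- file.path(outdir, "confusion.csv")
  utils::write.csv(cm, p)
  paths <- c(paths, p)
  p <- file.path(outdir, "per_subject_accuracy.csv")
  utils::write.csv(report@perSubject, p, row.names = FALSE)
  paths <- c(paths, p)
  for (f in report@folds) {
    if (is.null(f$history)) next
    p <- file.path(outdir, sprintf("history_fold%02d.csv", f$fold))
    utils::write.csv(f$history, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(report@attention)) {
    p <- file.path(outdir, sprintf("attention_%s.csv", nm))
    utils::write.table(report@attention[[nm]], p, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
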