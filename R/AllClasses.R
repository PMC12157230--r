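#' @include AllGenerics.R
NULL

# Central data model. All containers are plain S4 with validity checks;
# masks use TRUE = missing, matching the "explicit missingness" convention
# used throughout the conditioning pipeline.

#' Sensor sites, state labels and rate constants
#'
#' Six bilateral lower-limb sensor sites (tibialis anterior, gastrocnemius
#' lateralis, rectus femoris; L/R suffix), the two fatigue-state labels, and
#' the native sampling rates of the wearable platform: IMU channels at 148 Hz,
#' sEMG at 1259 Hz. All channels are resampled onto the IMU rate after
#' conditioning, so one 3 s analysis window spans \code{round(3 * 148) = 444}
#' frames.
#'
#' @name gaitFatigue-constants
#' @aliases sensorSites fatigueStates
NULL

#' @rdname gaitFatigue-constants
#' @export
sensorSites <- function() c("TAL", "TAR", "GLL", "GLR", "RFL", "RFR")

#' @rdname gaitFatigue-constants
#' @export
fatigueStates <- function() c("non_fatigued", "fatigued")

IMU_RATE <- 148
EMG_RATE <- 1259
WINDOW_FRAMES <- 444L  # round(3 s * 148 Hz)
HOP_FRAMES <- 222L     # 50 % overlap

.isState <- function(x) length(x) == 1L && x %in% fatigueStates()
.isSite <- function(x) length(x) == 1L && x %in% sensorSites()

#' RawRecording: one subject x state x site multi-rate sensor block
#'
#' Holds the unconditioned signals of a single wearable sensor: 3-axis
#' accelerometer and 3-axis gyroscope sampled at the IMU rate, and one sEMG
#' channel sampled at the (much higher) EMG rate. Missingness is carried as
#' logical masks (TRUE = missing) rather than sentinel values so that gap
#' interpolation can act on explicit gaps. IMU and EMG streams must cover the
#' same wall-clock duration (within 0.05 s).
#'
#' Units are fixed by convention to m/s^2 (accelerometer), rad/s (gyroscope)
#' and mV (sEMG); no conversion is performed anywhere in the pipeline.
#'
#' @slot subjectId character scalar.
#' @slot state \code{"non_fatigued"} or \code{"fatigued"}.
#' @slot site one of \code{sensorSites()}.
#' @slot acc,gyro numeric matrices (samples x 3), columns x/y/z.
#' @slot emg numeric vector.
#' @slot accMask,gyroMask logical matrices, \code{TRUE} = missing.
#' @slot emgMask logical vector.
#' @slot imuRate,emgRate sampling rates in Hz.
#' @exportClass RawRecording
setClass("RawRecording",
  slots = c(
    subjectId = "character", state = "character", site = "character",
    acc = "matrix", gyro = "matrix", emg = "numeric",
    accMask = "matrix", gyroMask = "matrix", emgMask = "logical",
    imuRate = "numeric", emgRate = "numeric"
  )
)

setValidity("RawRecording", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a non-empty scalar")
  if (!.isState(object@state))
    msg <- c(msg, sprintf("state must be one of: %s",
                          paste(fatigueStates(), collapse = ", ")))
  if (!.isSite(object@site))
    msg <- c(msg, sprintf("site must be one of: %s",
                          paste(sensorSites(), collapse = ", ")))
  if (ncol(object@acc) != 3L) msg <- c(msg, "acc must have 3 columns (x,y,z)")
  if (ncol(object@gyro) != 3L) msg <- c(msg, "gyro must have 3 columns (x,y,z)")
  if (nrow(object@acc) != nrow(object@gyro))
    msg <- c(msg, "acc and gyro must have equal sample counts")
  if (!identical(dim(object@accMask), dim(object@acc)))
    msg <- c(msg, "accMask must match acc dimensions")
  if (!identical(dim(object@gyroMask), dim(object@gyro)))
    msg <- c(msg, "gyroMask must match gyro dimensions")
  if (length(object@emgMask) != length(object@emg))
    msg <- c(msg, "emgMask must match emg length")
  if (object@imuRate <= 0 || object@emgRate <= 0)
    msg <- c(msg, "sampling rates must be positive")
  durImu <- nrow(object@acc) / object@imuRate
  durEmg <- length(object@emg) / object@emgRate
  if (nrow(object@acc) > 0L && abs(durImu - durEmg) > 0.05)
    msg <- c(msg, sprintf(
      "IMU (%.3f s) and EMG (%.3f s) durations disagree by more than 0.05 s",
      durImu, durEmg))
  if (any(!is.finite(object@acc[!object@accMask])))
    msg <- c(msg, "acc has non-finite values outside the missing mask")
  if (any(!is.finite(object@gyro[!object@gyroMask])))
    msg <- c(msg, "gyro has non-finite values outside the missing mask")
  if (any(!is.finite(object@emg[!object@emgMask])))
    msg <- c(msg, "emg has non-finite values outside the missing mask")
  if (length(msg)) msg else TRUE
})

#' CohortManifest: index of a cohort's recording files
#'
#' One row per (subject, state, site) triple, pointing at the IMU and EMG
#' delimited-text files of that sensor. Only (subject, state) groups with all
#' six sites present are retained by \code{\link{readManifest}}; incomplete
#' groups are reported and excluded.
#'
#' @slot entries data.frame with columns subject, state, site, imu_path,
#'   emg_path.
#' @slot imuRate,emgRate declared sampling rates (Hz).
#' @slot root directory that relative paths are resolved against.
#' @exportClass CohortManifest
setClass("CohortManifest",
  slots = c(entries = "data.frame", imuRate = "numeric",
            emgRate = "numeric", root = "character")
)

setValidity("CohortManifest", function(object) {
  msg <- character(0)
  need <- c("subject", "state", "site", "imu_path", "emg_path")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, sprintf("entries must have columns: %s",
                          paste(need, collapse = ", ")))
  else {
    key <- with(object@entries, paste(subject, state, site))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (subject, state, site) triples in manifest")
    if (!all(object@entries$state %in% fatigueStates()))
      msg <- c(msg, "unknown state label in manifest")
    if (!all(object@entries$site %in% sensorSites()))
      msg <- c(msg, "unknown site label in manifest")
    grp <- split(object@entries$site, paste(object@entries$subject,
                                            object@entries$state, sep = "|"))
    bad <- names(grp)[vapply(grp, function(s)
      !setequal(s, sensorSites()), logical(1))]
    if (length(bad))
      msg <- c(msg, sprintf("incomplete site groups: %s",
                            paste(bad, collapse = "; ")))
  }
  if (length(msg)) msg else TRUE
})

#' ProcessedRecording: one subject-state on the common 148 Hz grid
#'
#' All conditioned channels of one subject in one fatigue state, stacked as a
#' frames x channels matrix on the common frame rate. Per IMU site the matrix
#' carries three linear-jerk and three angular-jerk channels; per site one
#' smoothed EMG envelope. Channel names follow
#' \code{"<site>.<linjerk|angjerk>.<x|y|z>"} / \code{"<site>.emg"}.
#'
#' @slot subjectId,state as in \linkS4class{RawRecording}.
#' @slot data numeric matrix, frames x channels, all finite.
#' @slot channelNames character vector, one per column.
#' @slot rate frame rate in Hz (148).
#' @exportClass ProcessedRecording
setClass("ProcessedRecording",
  slots = c(subjectId = "character", state = "character",
            data = "matrix", channelNames = "character", rate = "numeric")
)

setValidity("ProcessedRecording", function(object) {
  msg <- character(0)
  if (!.isState(object@state)) msg <- c(msg, "invalid state")
  if (length(object@channelNames) != ncol(object@data))
    msg <- c(msg, "channelNames must match data columns")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "duplicated channel names")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "processed data must be finite everywhere")
  if (length(msg)) msg else TRUE
})

#' SegmentSet: the model-ready windowed dataset
#'
#' 3-D array of z-scored analysis windows (segments x frames x channels) with
#' per-segment subject id and binary fatigue label (0 = non-fatigued,
#' 1 = fatigued). The canonical window is 444 frames (3 s at 148 Hz) with a
#' 222-frame hop (50 % overlap).
#'
#' @slot data numeric array, segments x frames x channels.
#' @slot labels integer vector in \{0, 1\}.
#' @slot subjects character vector, one per segment.
#' @slot channelNames character vector, one per channel.
#' @slot windowFrames,hopFrames window geometry in frames.
#' @exportClass SegmentSet
setClass("SegmentSet",
  slots = c(data = "array", labels = "integer", subjects = "character",
            channelNames = "character", windowFrames = "integer",
            hopFrames = "integer")
)

setValidity("SegmentSet", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-D array")
  else {
    if (length(object@labels) != d[1L])
      msg <- c(msg, "labels must have one entry per segment")
    if (length(object@subjects) != d[1L])
      msg <- c(msg, "subjects must have one entry per segment")
    if (length(object@channelNames) != d[3L])
      msg <- c(msg, "channelNames must match channel dimension")
  }
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (length(msg)) msg else TRUE
})

#' CombinationSpec: one row of the sensor/signal combination registry
#'
#' An ordered channel-selection recipe: which sites and signal types
#' (EMG envelope, 3-axis linear jerk, 3-axis angular jerk) feed the
#' classifier. The registry holds 14 such configurations spanning EMG-only,
#' jerk-only, single-leg hybrid and comprehensive setups.
#'
#' @slot id integer 1..14.
#' @slot category grouping label.
#' @slot label human-readable description.
#' @slot channels ordered character vector of resolved channel names.
#' @slot nFeatures expanded channel count (EMG = 1, jerk = 3 per site/type).
#' @exportClass CombinationSpec
setClass("CombinationSpec",
  slots = c(id = "integer", category = "character", label = "character",
            channels = "character", nFeatures = "integer")
)

setValidity("CombinationSpec", function(object) {
  msg <- character(0)
  if (object@id < 1L || object@id > 14L) msg <- c(msg, "id must be in 1..14")
  if (object@nFeatures != length(object@channels))
    msg <- c(msg, "nFeatures must equal the expanded channel count")
  if (length(msg)) msg else TRUE
})

#' TrainedFatigueModel: a fitted CNN-LSTM-Attention classifier
#'
#' Fitted parameters plus the training history (per-epoch train/validation
#' loss and accuracy), the resolved configuration snapshot, and the channel
#' layout the model was trained on. Class index 1 is "non_fatigued" (label 0),
#' index 2 "fatigued" (label 1).
#'
#' @slot params named list of weight matrices/vectors.
#' @slot config resolved model configuration (see \code{\link{modelConfig}}).
#' @slot history data.frame: epoch, trainLoss, trainAcc, valLoss, valAcc, lr.
#' @slot channelNames channels (in order) the model expects.
#' @slot classes label names, index 1 = class 0.
#' @exportClass TrainedFatigueModel
setClass("TrainedFatigueModel",
  slots = c(params = "list", config = "list", history = "data.frame",
            channelNames = "character", classes = "character")
)

setValidity("TrainedFatigueModel", function(object) {
  msg <- character(0)
  if (nrow(object@history) > 0L &&
      !all(c("trainLoss", "trainAcc", "valLoss", "valAcc") %in%
           names(object@history)))
    msg <- c(msg, "history must carry loss and accuracy tracks")
  if (length(object@classes) != 2L)
    msg <- c(msg, "binary classifier requires exactly 2 classes")
  if (length(msg)) msg else TRUE
})

#' EvalReport: cross-validated evaluation of one combination
#'
#' Per-fold predictions and confusion counts, the pooled confusion matrix,
#' accuracy / per-class precision / recall / F1, a per-subject accuracy table,
#' attention maps of representative test segments, and per-fold training
#' histories.
#'
#' @slot protocol \code{"losocv"} or \code{"kfold9"}.
#' @slot combinationId combination evaluated.
#' @slot folds list, one element per fold (indices, predictions, counts).
#' @slot pooled named numeric vector TP/FP/TN/FN (fatigued = positive).
#' @slot metrics data.frame of pooled and macro-averaged metrics per class.
#' @slot perSubject data.frame: subject, nSegments, accuracy.
#' @slot attention list of attention matrices for representative segments.
#' @slot seed integer seed that reproduces the report.
#' @exportClass EvalReport
setClass("EvalReport",
  slots = c(protocol = "character", combinationId = "integer",
            folds = "list", pooled = "numeric", metrics = "data.frame",
            perSubject = "data.frame", attention = "list", seed = "integer")
)

setValidity("EvalReport", function(object) {
  msg <- character(0)
  if (!object@protocol %in% c("losocv", "kfold9"))
    msg <- c(msg, "protocol must be losocv or kfold9")
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(object@pooled)))
    msg <- c(msg, "pooled counts must be named TP/FP/TN/FN")
  else if (any(object@pooled[need] < 0))
    msg <- c(msg, "confusion counts must be non-negative")
  if (length(msg)) msg else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording %s / %s / %s\n", object@subjectId, object@state,
              object@site))
  cat(sprintf("  IMU: %d samples @ %g Hz (%.2f s), %d masked\n",
              nrow(object@acc), object@imuRate,
              nrow(object@acc) / object@imuRate,
              sum(object@accMask) + sum(object@gyroMask)))
  cat(sprintf("  EMG: %d samples @ %g Hz, %d masked\n",
              length(object@emg), object@emgRate, sum(object@emgMask)))
})

setMethod("show", "CohortManifest", function(object) {
  grp <- unique(object@entries[, c("subject", "state")])
  cat(sprintf("CohortManifest: %d subjects, %d complete recording groups, %d files\n",
              length(unique(object@entries$subject)), nrow(grp),
              2L * nrow(object@entries)))
  cat(sprintf("  rates: IMU %g Hz, EMG %g Hz; root: %s\n",
              object@imuRate, object@emgRate, object@root))
})

setMethod("show", "ProcessedRecording", function(object) {
  cat(sprintf("ProcessedRecording %s / %s: %d frames x %d channels @ %g Hz\n",
              object@subjectId, object@state, nrow(object@data),
              ncol(object@data), object@rate))
})

setMethod("show", "SegmentSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("SegmentSet: %d segments x %d frames x %d channels\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  subjects: %d; labels: %d non-fatigued / %d fatigued\n",
              length(unique(object@subjects)),
              sum(object@labels == 0L), sum(object@labels == 1L)))
})

setMethod("show", "CombinationSpec", function(object) {
  cat(sprintf("CombinationSpec %d [%s]: %s\n", object@id, object@category,
              object@label))
  cat(sprintf("  %d features: %s\n", object@nFeatures,
              paste(object@channels, collapse = ", ")))
})

setMethod("show", "TrainedFatigueModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("TrainedFatigueModel: %d channels, %d parameters, %d epochs trained\n",
              length(object@channelNames), np, nrow(object@history)))
  if (nrow(object@history) > 0L) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  final: train acc %.4f / loss %.4f; val acc %.4f / loss %.4f\n",
                last$trainAcc, last$trainLoss, last$valAcc, last$valLoss))
  }
})

setMethod("show", "EvalReport", function(object) {
  m <- computeMetrics(object@pooled)
  cat(sprintf("EvalReport [%s, combination %d]: %d folds, %d test segments\n",
              object@protocol, object@combinationId, length(object@folds),
              sum(object@pooled)))
  cat(sprintf("  pooled accuracy %.4f; recall(F) %.4f; recall(NF) %.4f\n",
              m$accuracy, m$recall, m$recallNegative))
})

# ---- basic accessors --------------------------------------------------------

#' @rdname nSegments
#' @export
setMethod("nSegments", "SegmentSet", function(x) dim(x@data)[1L])

#' @rdname channelNames
#' @export
setMethod("channelNames", "SegmentSet", function(x) x@channelNames)

#' @rdname channelNames
#' @export
setMethod("channelNames", "ProcessedRecording", function(x) x@channelNames)

#' @rdname segmentData
#' @export
setMethod("segmentData", "SegmentSet", function(x) x@data)

#' @rdname segmentLabels
#' @export
setMethod("segmentLabels", "SegmentSet", function(x) x@labels)

#' @rdname segmentSubjects
#' @export
setMethod("segmentSubjects", "SegmentSet", function(x) x@subjects)
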