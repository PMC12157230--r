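#' @include AllClasses.R
NULL

#' Cut a processed recording into fixed overlapping windows
#'
#' Windows of \code{windowS} seconds with fractional \code{overlap} start at
#' multiples of the hop \code{window * (1 - overlap)}; the number of full
#' windows is \code{floor((L - W) / H) + 1} and any tail remainder is
#' discarded. With the defaults (3 s, 50 \%, 148 Hz) the window is 444 frames
#' and the hop 222.
#'
#' @param rec A \linkS4class{ProcessedRecording}.
#' @param windowS window length in seconds.
#' @param overlap fractional overlap in [0, 1).
#' @param maxWindows optional cap; windows beyond it (counted from the start
#'   of the recording) are discarded.
#' @return List of frames x channels matrices.
#' @export
segmentWindows <- function(rec, windowS = 3, overlap = 0.5,
                           maxWindows = NULL) {
  W <- as.integer(round(windowS * rec@rate))
  H <- as.integer(round(W * (1 - overlap)))
  if (H < 1L) stop("segmentWindows: overlap too large")
  L <- nrow(rec@data)
  if (L < W)
    stop(sprintf("segmentWindows: recording (%d frames) shorter than one window (%d)",
                 L, W))
  n <- (L - W) %/% H + 1L
  if (!is.null(maxWindows)) n <- min(n, as.integer(maxWindows))
  lapply(seq_len(n) - 1L, function(i)
    rec@data[(i * H + 1L):(i * H + W), , drop = FALSE])
}

#' Per-segment, per-channel z-score normalisation
#'
#' Each channel of the window is centred and scaled by its own mean and SD
#' within the window; a zero-variance channel becomes all zeros. The scope is
#' deliberately per-segment: normalisation then never uses statistics from
#' other subjects, which keeps subject-independent evaluation honest.
#'
#' @param seg numeric matrix, frames x channels.
#' @param eps variance threshold below which a channel is treated as
#'   constant (default 0).
#' @return Normalised matrix of the same shape.
#' @export
zscoreSegment <- function(seg, eps = 0) {
  mu <- colMeans(seg)
  sd <- apply(seg, 2L, stats::sd)
  out <- sweep(seg, 2L, mu, "-")
  nz <- sd > eps & is.finite(sd)
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, sd[nz], "/")
  out[, !nz] <- 0
  out
}

#' Assemble the labelled windowed dataset
#'
#' Cuts every processed recording into exactly \code{windowsPerRecording}
#' windows, z-scores each window per channel, and stacks everything into a
#' \linkS4class{SegmentSet} ordered by (subject, state, window index).
#' Every subject must contribute both fatigue states; the class balance of
#' the result is therefore exact by construction. A cohort of 35 subjects
#' yields 630 segments (35 x 2 x 9).
#'
#' @param recordings list of \linkS4class{ProcessedRecording}s.
#' @param windowsPerRecording windows kept per recording (default 9).
#' @param windowS,overlap window geometry, see \code{\link{segmentWindows}}.
#' @param dropShort if \code{TRUE}, subjects whose recordings cannot supply
#'   the required windows are dropped with a warning instead of aborting.
#' @return A \linkS4class{SegmentSet}.
#' @export
assembleDataset <- function(recordings, windowsPerRecording = 9,
                            windowS = 3, overlap = 0.5, dropShort = FALSE) {
  if (!length(recordings)) stop("assembleDataset: no recordings")
  chan <- recordings[[1L]]@channelNames
  for (r in recordings)
    if (!identical(r@channelNames, chan))
      stop("assembleDataset: inconsistent channel layouts across recordings")
  meta <- data.frame(
    subject = vapply(recordings, function(r) r@subjectId, character(1)),
    state = vapply(recordings, function(r) r@state, character(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(meta))
    stop("assembleDataset: duplicate (subject, state) recordings")
  tab <- table(meta$subject)
  unpaired <- names(tab)[tab != 2L]
  if (length(unpaired))
    stop("assembleDataset: subjects without both fatigue states: ",
         paste(unpaired, collapse = ", "))
  ord <- order(meta$subject, match(meta$state, fatigueStates()))
  recordings <- recordings[ord]; meta <- meta[ord, ]

  segs <- list(); labels <- integer(0); subjects <- character(0)
  short <- character(0)
  for (i in seq_along(recordings)) {
    w <- tryCatch(
      segmentWindows(recordings[[i]], windowS, overlap,
                     maxWindows = windowsPerRecording),
      error = function(e) NULL)
    if (is.null(w) || length(w) < windowsPerRecording) {
      short <- c(short, meta$subject[i]); next
    }
    segs <- c(segs, lapply(w, zscoreSegment))
    labels <- c(labels,
                rep(match(meta$state[i], fatigueStates()) - 1L,
                    windowsPerRecording))
    subjects <- c(subjects, rep(meta$subject[i], windowsPerRecording))
  }
  short <- unique(short)
  if (length(short)) {
    if (!dropShort)
      stop("assembleDataset: recordings too short for ", windowsPerRecording,
           " windows: ", paste(short, collapse = ", "))
    warning("dropping short-recording subjects: ",
            paste(short, collapse = ", "))
    keep <- !(subjects %in% short)
    segs <- segs[keep]; labels <- labels[keep]; subjects <- subjects[keep]
    if (!length(segs)) stop("assembleDataset: no usable recordings left")
  }
  W <- nrow(segs[[1L]]); C <- ncol(segs[[1L]])
  data <- array(0, dim = c(length(segs), W, C))
  for (i in seq_along(segs)) data[i, , ] <- segs[[i]]
  methods::new("SegmentSet", data = data, labels = labels,
               subjects = subjects, channelNames = chan,
               windowFrames = as.integer(W),
               hopFrames = as.integer(round(W * (1 - overlap))))
}

#' Subset a SegmentSet by segment index
#'
#' @param x A \linkS4class{SegmentSet}.
#' @param i integer or logical segment indices.
#' @return A \linkS4class{SegmentSet} with the selected segments.
#' @export
subsetSegments <- function(x, i) {
  methods::new("SegmentSet",
    data = x@data[i, , , drop = FALSE],
    labels = x@labels[i], subjects = x@subjects[i],
    channelNames = x@channelNames,
    windowFrames = x@windowFrames, hopFrames = x@hopFrames)
}
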