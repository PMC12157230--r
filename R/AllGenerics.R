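#' Number of segments in a SegmentSet
#'
#' @param x A \linkS4class{SegmentSet}.
#' @return Integer scalar.
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' Channel names of a signal container
#'
#' @param x A \linkS4class{ProcessedRecording} or \linkS4class{SegmentSet}.
#' @return Character vector of channel names (\code{"<site>.<modality>[.axis]"}).
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Segment data array
#'
#' @param x A \linkS4class{SegmentSet}.
#' @return Numeric array \code{segments x frames x channels}.
#' @export
setGeneric("segmentData", function(x) standardGeneric("segmentData"))

#' Per-segment binary fatigue labels
#'
#' @param x A \linkS4class{SegmentSet}.
#' @return Integer vector of 0 (non-fatigued) / 1 (fatigued).
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' Per-segment subject identifiers
#'
#' @param x A \linkS4class{SegmentSet}.
#' @return Character vector, one entry per segment.
#' @export
setGeneric("segmentSubjects", function(x) standardGeneric("segmentSubjects"))

#' Select the channels of a sensor/signal combination
#'
#' @param x A \linkS4class{SegmentSet}.
#' @param spec A \linkS4class{CombinationSpec} (or a combination id 1-14).
#' @return A \linkS4class{SegmentSet} restricted to the combination's channels,
#'   in the combination's channel order; segment order and labels unchanged.
#' @export
setGeneric("selectChannels", function(x, spec) standardGeneric("selectChannels"))
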