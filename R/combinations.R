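#' @include AllClasses.R AllGenerics.R
NULL

# Registry of the 14 sensor/signal configurations evaluated against each
# other. EMG channels come first within a combination; jerk blocks expand to
# their three axes in (x, y, z) order. Feature counts: EMG envelope = 1
# channel, each jerk type = 3 channels per site.

.jerk <- function(site, type) paste0(site, ".", type, ".", c("x", "y", "z"))
.emg <- function(site) paste0(site, ".emg")

.combinationRegistry <- function() {
  list(
    list(id = 1L, category = "bilateral_unilateral_GL_EMG",
         label = "GLL (EMG)", channels = .emg("GLL")),
    list(id = 2L, category = "bilateral_unilateral_GL_EMG",
         label = "GLR (EMG)", channels = .emg("GLR")),
    list(id = 3L, category = "bilateral_unilateral_GL_EMG",
         label = "GLL and GLR (EMG)", channels = c(.emg("GLL"), .emg("GLR"))),
    list(id = 4L, category = "TA_jerk",
         label = "TAL and TAR (linear jerk)",
         channels = c(.jerk("TAL", "linjerk"), .jerk("TAR", "linjerk"))),
    list(id = 5L, category = "TA_jerk",
         label = "TAL and TAR (angular jerk)",
         channels = c(.jerk("TAL", "angjerk"), .jerk("TAR", "angjerk"))),
    list(id = 6L, category = "TA_jerk",
         label = "TAL and TAR (linear jerk, angular jerk)",
         channels = c(.jerk("TAL", "linjerk"), .jerk("TAL", "angjerk"),
                      .jerk("TAR", "linjerk"), .jerk("TAR", "angjerk"))),
    list(id = 7L, category = "RF_jerk",
         label = "RFL and RFR (linear jerk)",
         channels = c(.jerk("RFL", "linjerk"), .jerk("RFR", "linjerk"))),
    list(id = 8L, category = "RF_jerk",
         label = "RFL and RFR (angular jerk)",
         channels = c(.jerk("RFL", "angjerk"), .jerk("RFR", "angjerk"))),
    list(id = 9L, category = "RF_jerk",
         label = "RFL and RFR (linear jerk, angular jerk)",
         channels = c(.jerk("RFL", "linjerk"), .jerk("RFL", "angjerk"),
                      .jerk("RFR", "linjerk"), .jerk("RFR", "angjerk"))),
    list(id = 10L, category = "single_leg_hybrid",
         label = "GLL EMG, TAL (linear jerk, angular jerk)",
         channels = c(.emg("GLL"), .jerk("TAL", "linjerk"),
                      .jerk("TAL", "angjerk"))),
    list(id = 11L, category = "single_leg_hybrid",
         label = "GLL EMG, RFL (linear jerk)",
         channels = c(.emg("GLL"), .jerk("RFL", "linjerk"))),
    list(id = 12L, category = "single_leg_hybrid",
         label = "TAL (linear jerk, angular jerk), RFL (linear jerk)",
         channels = c(.jerk("TAL", "linjerk"), .jerk("TAL", "angjerk"),
                      .jerk("RFL", "linjerk"))),
    list(id = 13L, category = "single_leg_hybrid",
         label = "GLL EMG, TAL (linear jerk, angular jerk), RFL (linear jerk)",
         channels = c(.emg("GLL"), .jerk("TAL", "linjerk"),
                      .jerk("TAL", "angjerk"), .jerk("RFL", "linjerk"))),
    list(id = 14L, category = "comprehensive",
         label = paste("GLL and GLR EMG, TAL and TAR (linear jerk, angular",
                       "jerk), RFL and RFR (linear jerk)"),
         channels = c(.emg("GLL"), .emg("GLR"),
                      .jerk("TAL", "linjerk"), .jerk("TAL", "angjerk"),
                      .jerk("TAR", "linjerk"), .jerk("TAR", "angjerk"),
                      .jerk("RFL", "linjerk"), .jerk("RFR", "linjerk")))
  )
}

#' Retrieve one sensor/signal combination
#'
#' @param id integer combination id, 1 to 14.
#' @return A \linkS4class{CombinationSpec}.
#' @examples
#' getCombination(3)   # bilateral GL EMG, 2 features
#' getCombination(13)  # single-leg hybrid, 10 features
#' @export
getCombination <- function(id) {
  reg <- .combinationRegistry()
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > length(reg))
    stop("unknown combination id: must be an integer in 1..", length(reg))
  e <- reg[[id]]
  methods::new("CombinationSpec", id = e$id, category = e$category,
               label = e$label, channels = e$channels,
               nFeatures = length(e$channels))
}

#' Tabulate the whole combination registry
#'
#' @return data.frame with columns id, category, label, nFeatures.
#' @export
listCombinations <- function() {
  reg <- .combinationRegistry()
  data.frame(
    id = vapply(reg, `[[`, integer(1), "id"),
    category = vapply(reg, `[[`, character(1), "category"),
    label = vapply(reg, `[[`, character(1), "label"),
    nFeatures = vapply(reg, function(e) length(e$channels), integer(1)),
    stringsAsFactors = FALSE)
}

#' @rdname selectChannels
#' @export
setMethod("selectChannels", signature("SegmentSet", "CombinationSpec"),
  function(x, spec) {
    pos <- match(spec@channels, x@channelNames)
    if (anyNA(pos))
      stop("selectChannels: channels absent from SegmentSet: ",
           paste(spec@channels[is.na(pos)], collapse = ", "))
    methods::new("SegmentSet",
      data = x@data[, , pos, drop = FALSE],
      labels = x@labels, subjects = x@subjects,
      channelNames = x@channelNames[pos],
      windowFrames = x@windowFrames, hopFrames = x@hopFrames)
  })

#' @rdname selectChannels
#' @export
setMethod("selectChannels", signature("SegmentSet", "numeric"),
  function(x, spec) selectChannels(x, getCombination(spec)))
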