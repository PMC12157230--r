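# Shared fixtures, built in code and cached for the duration of the run.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]]))
    assign(name, builder(), envir = .fixtureCache)
  .fixtureCache[[name]]
}

# Small labelled SegmentSet of pure noise with an injected class difference:
# class 1 segments carry a mid-frequency burst on channel 1.
toySegmentSet <- function(n = 40L, frames = 444L, channels = 2L,
                          nSubjects = 8L, effect = 3, seed = 1L) {
  set.seed(seed)
  stopifnot(n %% 2L == 0L)
  X <- array(rnorm(n * frames * channels), c(n, frames, channels))
  y <- rep(c(0L, 1L), each = n %/% 2L)
  for (i in which(y == 1L)) {
    t0 <- sample(seq(50L, frames - 120L), 1L)
    X[i, t0:(t0 + 60L), 1L] <- X[i, t0:(t0 + 60L), 1L] +
      effect * sin(2 * pi * 8 * (0:60) / 148)
  }
  methods::new("SegmentSet", data = X, labels = y,
               subjects = rep(sprintf("S%02d", seq_len(nSubjects)),
                              length.out = n),
               channelNames = paste0("ch", seq_len(channels)),
               windowFrames = as.integer(frames), hopFrames = 222L)
}

# Tiny model configuration for fast unit tests (not the small experiment
# configuration; this one is deliberately minimal).
tinyModelConfig <- function(...) {
  args <- utils::modifyList(
    list(convFilters = c(2L, 3L), convKernels = c(5L, 3L),
         poolSizes = c(2L, 2L), lstmUnits = 3L, denseUnits = 3L,
         dropout = 0, maxEpochs = 5L, patience = 3L, lrPatience = 2L,
         batchSize = 8L, seed = 7L),
    list(...))
  do.call(modelConfig, args)
}

# A four-subject default-gain synthetic cohort, segmented; used by several
# test files.
smallCohortSegments <- function() {
  cachedFixture("smallCohortSegments", function()
    simulateSegmentSet(simulationParams(nSubjects = 4L, seed = 11L)))
}

# Build a ProcessedRecording directly from a channel matrix.
processedRecording <- function(data, subject = "S01",
                               state = "non_fatigued", rate = 148) {
  methods::new("ProcessedRecording", subjectId = subject, state = state,
               data = data,
               channelNames = paste0("ch", seq_len(ncol(data))),
               rate = rate)
}

# Write a cohort manifest JSON from an entries data.frame; returns the path.
writeManifestJSON <- function(entries, dir = NULL,
                              imuRate = 148, emgRate = 1259) {
  if (is.null(dir)) {
    dir <- tempfile("manifest")
    dir.create(dir)
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(imu_rate = imuRate, emg_rate = emgRate,
                            entries = entries),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

# Full 6-site entries for the given subjects/states.
manifestEntries <- function(subjects, states = fatigueStates()) {
  do.call(rbind, lapply(subjects, function(s)
    do.call(rbind, lapply(states, function(st)
      data.frame(subject = s, state = st, site = sensorSites(),
                 imu_path = sprintf("%s_%s_%s_imu.csv", s, st, sensorSites()),
                 emg_path = sprintf("%s_%s_%s_emg.csv", s, st, sensorSites()),
                 stringsAsFactors = FALSE)))))
}
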