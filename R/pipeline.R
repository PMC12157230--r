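#' @include AllClasses.R synthetic.R evaluation.R
NULL

#' Assemble and validate a full experiment configuration
#'
#' @param combination combination id (1..14).
#' @param protocol \code{"losocv"} or \code{"kfold9"}.
#' @param model a \code{\link{modelConfig}}.
#' @param simulation a \code{\link{simulationParams}}, or \code{NULL} when
#'   \code{inputDir} points at an existing cohort.
#' @param inputDir directory holding a cohort \code{manifest.json}
#'   (\code{NULL} = simulate).
#' @param outDir artifact directory (\code{NULL} = no artifacts written).
#' @param windowS,overlap,windowsPerRecording segmentation geometry.
#' @param filters a \code{\link{filterSpec}}.
#' @param seed master seed; overrides the model and simulation seeds so one
#'   integer pins the whole run.
#' @return Validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(combination = 13, protocol = "losocv",
                      model = smallModelConfig(),
                      simulation = simulationParams(),
                      inputDir = NULL, outDir = NULL,
                      windowS = 3, overlap = 0.5, windowsPerRecording = 9,
                      filters = filterSpec(), seed = 1L) {
  cfg <- list(combination = combination, protocol = protocol,
              model = model, simulation = simulation,
              inputDir = inputDir, outDir = outDir,
              windowS = windowS, overlap = overlap,
              windowsPerRecording = windowsPerRecording,
              filters = filters, seed = as.integer(seed))
  errs <- validateConfig(cfg)
  if (length(errs))
    stop("invalid RunConfig:\n  - ", paste(errs, collapse = "\n  - "))
  cfg$model$seed <- cfg$seed
  if (!is.null(cfg$simulation)) cfg$simulation$seed <- cfg$seed
  class(cfg) <- "RunConfig"
  cfg
}

#' Validate an experiment configuration
#'
#' Checks every cross-field constraint (band edges against sampling rates,
#' recording duration against the required window count, protocol and
#' combination validity) and returns the full list of problems rather than
#' stopping at the first.
#'
#' @param cfg a list shaped like \code{\link{runConfig}}'s arguments.
#' @return Character vector of error messages; empty when valid.
#' @export
validateConfig <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  comb <- suppressWarnings(as.integer(cfg$combination))
  chk(length(comb) == 1L && !is.na(comb) && comb >= 1L && comb <= 14L,
      sprintf("combination must be an integer in 1..14 (got %s)",
              deparse(cfg$combination)))
  chk(isTRUE(cfg$protocol %in% c("losocv", "kfold9")),
      "protocol must be 'losocv' or 'kfold9'")
  chk(inherits(cfg$model, "ModelConfig") || is.list(cfg$model),
      "model must be a modelConfig()")
  f <- cfg$filters
  if (inherits(f, "FilterSpec")) {
    chk(f$acc[2] < 148 / 2,
        sprintf("accel band high edge %g Hz >= IMU Nyquist %g Hz",
                f$acc[2], 148 / 2))
    chk(f$gyro[2] < 148 / 2,
        sprintf("gyro band high edge %g Hz >= IMU Nyquist %g Hz",
                f$gyro[2], 148 / 2))
    chk(f$emg[2] < 1259 / 2,
        sprintf("EMG band high edge %g Hz >= EMG Nyquist %g Hz",
                f$emg[2], 1259 / 2))
  } else errs <- c(errs, "filters must be a filterSpec()")
  chk(is.numeric(cfg$windowS) && cfg$windowS > 0, "windowS must be > 0")
  chk(is.numeric(cfg$overlap) && cfg$overlap >= 0 && cfg$overlap < 1,
      "overlap must be in [0, 1)")
  if (is.numeric(cfg$windowS) && is.numeric(cfg$overlap) &&
      cfg$overlap >= 0 && cfg$overlap < 1) {
    W <- round(cfg$windowS * 148)
    H <- round(W * (1 - cfg$overlap))
    need <- (W + (cfg$windowsPerRecording - 1) * H) / 148
    dur <- if (!is.null(cfg$simulation)) cfg$simulation$durationS else NULL
    if (!is.null(dur))
      chk(dur >= need,
          sprintf("duration %g s too short for %d windows (needs >= %.1f s)",
                  dur, cfg$windowsPerRecording, need))
  }
  chk(!is.null(cfg$simulation) || !is.null(cfg$inputDir),
      "either a simulation or an inputDir must be given")
  if (!is.null(cfg$inputDir))
    chk(file.exists(file.path(cfg$inputDir, "manifest.json")),
        sprintf("inputDir %s has no manifest.json", cfg$inputDir))
  errs
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[setdiff(names(cfg), "outDir")],
                              auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a full experiment: simulate/load, preprocess, segment, train, evaluate
#'
#' Executes the stage sequence of the pipeline under one seed: cohort
#' simulation (or loading from \code{inputDir}), per-recording conditioning,
#' window segmentation and normalisation, channel selection for the chosen
#' combination, cross-validated training/evaluation, and report rendering.
#' When \code{outDir} is set, the report artifacts plus a run manifest
#' (config hash, seed, package version) are written there. Reruns of an
#' identical configuration reproduce identical metrics.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @param segments optional precomputed \linkS4class{SegmentSet}; skips the
#'   simulate/preprocess/segment stages (used by
#'   \code{\link{runCombinationSweep}} to share one preprocessed cohort
#'   across combinations).
#' @param verbose print stage-level progress.
#' @return An \linkS4class{EvalReport}.
#' @export
runExperiment <- function(cfg, segments = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(segments)) {
    if (!is.null(cfg$inputDir)) {
      say("stage load: reading cohort from %s", cfg$inputDir)
      manifest <- readManifest(file.path(cfg$inputDir, "manifest.json"))
      groups <- recordingGroups(manifest)
      recs <- lapply(seq_len(nrow(groups)), function(i) {
        g <- readRecordingGroup(manifest, groups$subject[i], groups$state[i])
        preprocessRecording(g, cfg$filters)
      })
    } else {
      say("stage simulate+preprocess: %d subjects", cfg$simulation$nSubjects)
      recs <- list()
      for (s in seq_len(cfg$simulation$nSubjects))
        for (state in fatigueStates())
          recs[[length(recs) + 1L]] <- preprocessRecording(
            simulateRecording(cfg$simulation, s, state), cfg$filters)
    }
    say("stage segment: %d recordings", length(recs))
    segments <- assembleDataset(recs,
                                windowsPerRecording = cfg$windowsPerRecording,
                                windowS = cfg$windowS, overlap = cfg$overlap)
  }
  say("stage evaluate: combination %s, %s", cfg$combination, cfg$protocol)
  report <- runCV(segments, cfg$combination, cfg$protocol,
                  cfg = cfg$model, seed = cfg$seed)
  if (!is.null(cfg$outDir)) {
    say("stage report: %s", cfg$outDir)
    renderReports(report, cfg$outDir)
    jsonlite::write_json(
      list(config_hash = .configHash(cfg), seed = cfg$seed,
           package_version = as.character(utils::packageVersion("gaitFatigue")),
           r_version = R.version.string),
      file.path(cfg$outDir, "run_manifest.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' Evaluate several combinations on one preprocessed cohort
#'
#' Simulates (or loads) and preprocesses the cohort once, then runs
#' \code{\link{runCV}} for each requested combination — the
#' combination-sweep analogue of comparing sensor configurations side by
#' side.
#'
#' @param cfg a \code{\link{runConfig}} (its \code{combination} is ignored).
#' @param combinations integer vector of combination ids.
#' @param verbose print progress.
#' @return data.frame: combination, nFeatures, accuracy (pooled), plus the
#'   per-fold mean accuracy.
#' @export
runCombinationSweep <- function(cfg, combinations = 1:14, verbose = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"))
  base <- cfg
  base$outDir <- NULL
  segments <- NULL
  # build the shared SegmentSet once via a throwaway single run preparation
  if (!is.null(base$inputDir)) {
    manifest <- readManifest(file.path(base$inputDir, "manifest.json"))
    groups <- recordingGroups(manifest)
    recs <- lapply(seq_len(nrow(groups)), function(i)
      preprocessRecording(readRecordingGroup(manifest, groups$subject[i],
                                             groups$state[i]), base$filters))
  } else {
    recs <- list()
    for (s in seq_len(base$simulation$nSubjects))
      for (state in fatigueStates())
        recs[[length(recs) + 1L]] <- preprocessRecording(
          simulateRecording(base$simulation, s, state), base$filters)
  }
  segments <- assembleDataset(recs,
                              windowsPerRecording = base$windowsPerRecording,
                              windowS = base$windowS, overlap = base$overlap)
  rows <- lapply(combinations, function(cid) {
    if (verbose) message("combination ", cid)
    rep <- runCV(segments, cid, base$protocol, cfg = base$model,
                 seed = base$seed, keepHistories = FALSE)
    data.frame(combination = cid,
               nFeatures = getCombination(cid)@nFeatures,
               accuracy = pooledAccuracy(rep),
               meanFoldAccuracy = mean(vapply(rep@folds,
                 function(f) f$metrics$accuracy, numeric(1))))
  })
  do.call(rbind, rows)
}
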