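#' @include AllClasses.R recordings-io.R preprocess.R segmentation.R
NULL

# Synthetic six-site gait cohort. Each subject carries latent gait
# parameters (cadence, phase, per-site amplitude factors, harmonic mix)
# shared between their two recordings; the fatigued recording differs only
# through the effect multipliers: heel-strike transients scaled by jerkGain,
# EMG burst envelopes by emgGain, the left side additionally by
# asymmetryGain, and cadence by cadenceFactor. Gains act on the transient /
# burst components, not on whole channels, so the effects survive
# per-segment z-scoring - as fatigue signatures in real gait do.

.SITE_SIDE <- c(TAL = "L", TAR = "R", GLL = "L", GLR = "R",
                RFL = "L", RFR = "R")
.SITE_MUSCLE <- c(TAL = "TA", TAR = "TA", GLL = "GL", GLR = "GL",
                  RFL = "RF", RFR = "RF")
# heel-strike transient coupling per muscle site (shank strongest)
.SITE_TRANSIENT <- c(TA = 1.0, GL = 0.7, RF = 0.5)
# EMG burst centre within the stride cycle (radians)
.MUSCLE_BURST_PHASE <- c(TA = 0.0, GL = 2.8, RF = 0.9)

#' Parameters of the synthetic gait cohort
#'
#' Defaults describe a cohort of healthy walkers: ~0.9 strides/s cadence
#' with 5 \% log-normal between-subject jitter, 16 s recordings (enough for
#' nine 3 s windows at 50 \% overlap after preprocessing), stride-locked
#' accelerometer/gyroscope waveforms with damped heel-strike transients, and
#' stride-phase-gated band-limited EMG bursts synthesised at the native
#' 1259 Hz. Fatigue multiplies the heel-strike transients (\code{jerkGain}),
#' the EMG burst envelope (\code{emgGain}), the left side once more
#' (\code{asymmetryGain}) and slows cadence (\code{cadenceFactor}).
#'
#' @param nSubjects number of subjects (>= 2).
#' @param durationS recording length in seconds (>= 15.1).
#' @param cadenceHz baseline stride rate (strides/s).
#' @param cadenceJitterSd log-normal SD of per-subject cadence.
#' @param heelAmp heel-strike transient amplitude on the accelerometer
#'   (m/s^2).
#' @param transientFreq,transientTau transient oscillation frequency (Hz) and
#'   Gaussian envelope width (s).
#' @param gaitAccAmp,gyroAmp,gyroTransAmp stride-waveform amplitudes
#'   (m/s^2, rad/s, rad/s).
#' @param accNoiseSd,gyroNoiseSd,emgNoiseSd additive measurement-noise SDs.
#' @param emgBurstAmp,emgBaseline,emgKappa EMG burst envelope amplitude (mV),
#'   tonic baseline (mV), and von-Mises burst concentration.
#' @param jerkGain,emgGain,asymmetryGain,cadenceFactor fatigue effect
#'   multipliers (all > 0; 1 = no effect).
#' @param subjectAmpSd log-normal SD of per-subject, per-site amplitude
#'   factors.
#' @param dropoutRate fraction of samples masked as sensor dropout
#'   (short runs; 0 disables).
#' @param seed master seed; the whole cohort is a pure function of it.
#' @return Named list of class \code{"SimulationParams"}.
#' @export
simulationParams <- function(nSubjects = 8L, durationS = 16,
                             cadenceHz = 0.9, cadenceJitterSd = 0.05,
                             heelAmp = 4, transientFreq = 14,
                             transientTau = 0.012,
                             gaitAccAmp = 1.5, gyroAmp = 1.5,
                             gyroTransAmp = 1.0,
                             accNoiseSd = 0.08, gyroNoiseSd = 0.05,
                             emgBurstAmp = 0.3, emgBaseline = 0.02,
                             emgKappa = 4, emgNoiseSd = 0.01,
                             jerkGain = 1.3, emgGain = 1.25,
                             asymmetryGain = 1.2, cadenceFactor = 0.92,
                             subjectAmpSd = 0.15, dropoutRate = 0,
                             seed = 1L) {
  p <- as.list(environment())
  p$nSubjects <- as.integer(nSubjects)
  p$seed <- as.integer(seed)
  if (p$nSubjects < 2L) stop("simulationParams: need nSubjects >= 2")
  gains <- c(jerkGain, emgGain, asymmetryGain, cadenceFactor)
  if (any(gains <= 0)) stop("simulationParams: effect multipliers must be > 0")
  # slowest cadence still has to leave >= 9 windows: 2220 frames at 148 Hz
  if (durationS * 148 < 2220)
    stop("simulationParams: durationS too short for nine 3 s windows (need >= 15 s)")
  if (dropoutRate < 0 || dropoutRate > 0.2)
    stop("simulationParams: dropoutRate must be in [0, 0.2]")
  class(p) <- "SimulationParams"
  p
}

.recSeed <- function(params, subject, state, site = 0L) {
  stateIdx <- match(state, fatigueStates())
  ((params$seed %% 1000000L) * 1009L + subject * 613L +
     stateIdx * 89L + site * 7L) %% 2147483647L
}

.subjectLatents <- function(params, subject) {
  .withSeed((params$seed %% 1000000L) * 2003L + subject * 7919L, {
    sites <- sensorSites()
    list(
      cadence = params$cadenceHz * exp(stats::rnorm(1) *
                                         params$cadenceJitterSd),
      phase0 = stats::runif(1, 0, 2 * pi),
      harm2 = stats::runif(1, 0.3, 0.6),
      accAmp = stats::setNames(exp(stats::rnorm(6) * params$subjectAmpSd),
                               sites),
      gyroAmp = stats::setNames(exp(stats::rnorm(6) * params$subjectAmpSd),
                                sites),
      emgAmp = stats::setNames(exp(stats::rnorm(6) * params$subjectAmpSd),
                               sites),
      burstJitter = stats::setNames(stats::rnorm(6, 0, 0.15), sites)
    )
  })
}

.transientTrain <- function(t, strikes, amp, freq, tau) {
  out <- numeric(length(t))
  if (amp == 0) return(out)
  dt <- t[2L] - t[1L]
  half <- ceiling(4 * tau / dt)
  for (s in strikes) {
    c0 <- round(s / dt) + 1L
    i <- max(1L, c0 - half):min(length(t), c0 + half)
    if (!length(i)) next
    u <- t[i] - s
    out[i] <- out[i] + amp * exp(-0.5 * (u / tau)^2) * cos(2 * pi * freq * u)
  }
  out
}

.injectDropout <- function(x, rate) {
  n <- length(x)
  nRuns <- max(0L, round(rate * n / 3))
  mask <- logical(n)
  if (nRuns > 0L) {
    starts <- sample.int(n, nRuns)
    lens <- stats::rgeom(nRuns, 1 / 3) + 1L
    for (j in seq_len(nRuns))
      mask[starts[j]:min(n, starts[j] + lens[j] - 1L)] <- TRUE
  }
  x[mask] <- NA_real_
  list(x = x, mask = mask)
}

#' Simulate the six-site recording group of one subject-state
#'
#' Deterministic given the master seed in \code{params}: both states of a
#' subject share that subject's latent gait parameters and differ only
#' through the fatigue effect multipliers; left/right sites share the stride
#' phase with a half-cycle offset.
#'
#' @param params a \code{\link{simulationParams}}.
#' @param subject subject index (1-based).
#' @param state \code{"non_fatigued"} or \code{"fatigued"}.
#' @return Named list of six \linkS4class{RawRecording}s in
#'   \code{sensorSites()} order.
#' @export
simulateRecording <- function(params, subject, state) {
  stopifnot(inherits(params, "SimulationParams"))
  if (!.isState(state)) stop("simulateRecording: invalid state")
  lat <- .subjectLatents(params, subject)
  fat <- state == "fatigued"
  cad <- lat$cadence * if (fat) params$cadenceFactor else 1
  jerkG <- if (fat) params$jerkGain else 1
  emgG <- if (fat) params$emgGain else 1
  nI <- round(params$durationS * IMU_RATE)
  nE <- round(params$durationS * EMG_RATE)
  tI <- (seq_len(nI) - 1) / IMU_RATE
  tE <- (seq_len(nE) - 1) / EMG_RATE
  axPh <- c(0, 2 * pi / 3, 4 * pi / 3)
  axW <- c(1.0, 0.7, 0.5)
  trW <- c(1.0, 0.6, 0.3)
  subjectId <- sprintf("S%02d", subject)
  recs <- stats::setNames(vector("list", 6L), sensorSites())
  for (siteIdx in seq_along(sensorSites())) {
    site <- sensorSites()[siteIdx]
    side <- .SITE_SIDE[[site]]
    muscle <- .SITE_MUSCLE[[site]]
    asymG <- if (fat && side == "L") params$asymmetryGain else 1
    ph0 <- lat$phase0 + if (side == "R") pi else 0
    # heel strikes of this leg: stride phase crossing multiples of 2*pi
    kMax <- floor((2 * pi * cad * params$durationS + ph0) / (2 * pi))
    strikes <- (2 * pi * seq_len(max(kMax, 0L)) - ph0) / (2 * pi * cad)
    strikes <- strikes[strikes >= 0 & strikes <= params$durationS]
    .withSeed(.recSeed(params, subject, state, siteIdx), {
      phI <- 2 * pi * cad * tI + ph0
      tr <- .transientTrain(tI, strikes,
                            params$heelAmp * jerkG * asymG *
                              .SITE_TRANSIENT[[muscle]] * lat$accAmp[[site]],
                            params$transientFreq, params$transientTau)
      acc <- vapply(1:3, function(j) {
        a <- params$gaitAccAmp * lat$accAmp[[site]] * axW[j]
        a * (sin(phI + axPh[j]) + lat$harm2 * sin(2 * phI + 2 * axPh[j])) +
          trW[j] * tr + stats::rnorm(nI, 0, params$accNoiseSd)
      }, numeric(nI))
      trG <- .transientTrain(tI, strikes,
                             params$gyroTransAmp * jerkG * asymG *
                               .SITE_TRANSIENT[[muscle]] *
                               lat$gyroAmp[[site]],
                             params$transientFreq, params$transientTau)
      gyro <- vapply(1:3, function(j) {
        a <- params$gyroAmp * lat$gyroAmp[[site]] * axW[j]
        a * (sin(phI + axPh[j] + pi / 6) +
               lat$harm2 * sin(2 * phI + 2 * axPh[j])) +
          trW[j] * trG + stats::rnorm(nI, 0, params$gyroNoiseSd)
      }, numeric(nI))
      phE <- 2 * pi * cad * tE + ph0
      burstPh <- .MUSCLE_BURST_PHASE[[muscle]] + lat$burstJitter[[site]]
      envelope <- params$emgBaseline +
        params$emgBurstAmp * emgG * asymG * lat$emgAmp[[site]] *
          exp(params$emgKappa * (cos(phE - burstPh) - 1))
      carrier <- stats::rnorm(nE)
      bf <- signal::butter(4, c(20, 450) / (EMG_RATE / 2), type = "pass")
      carrier <- as.numeric(signal::filtfilt(bf, carrier))
      carrier <- carrier / stats::sd(carrier)
      emg <- envelope * carrier + stats::rnorm(nE, 0, params$emgNoiseSd)
      accMask <- matrix(FALSE, nI, 3L)
      gyroMask <- matrix(FALSE, nI, 3L)
      emgMask <- logical(nE)
      if (params$dropoutRate > 0) {
        for (j in 1:3) {
          d <- .injectDropout(acc[, j], params$dropoutRate)
          acc[, j] <- d$x; accMask[, j] <- d$mask
          d <- .injectDropout(gyro[, j], params$dropoutRate)
          gyro[, j] <- d$x; gyroMask[, j] <- d$mask
        }
        d <- .injectDropout(emg, params$dropoutRate)
        emg <- d$x; emgMask <- d$mask
      }
      recs[[site]] <- methods::new("RawRecording",
        subjectId = subjectId, state = state, site = site,
        acc = acc, gyro = gyro, emg = emg,
        accMask = accMask, gyroMask = gyroMask, emgMask = emgMask,
        imuRate = IMU_RATE, emgRate = EMG_RATE)
    })
  }
  recs
}

#' Simulate a cohort and write it to disk
#'
#' Writes \code{nSubjects x 2 states x 6 sites} recordings as the CSV dialect
#' of \code{\link{writeRecording}} plus a manifest JSON, all a deterministic
#' function of the master seed (same seed, byte-identical files).
#'
#' @param params a \code{\link{simulationParams}}.
#' @param dir output directory (created if needed).
#' @return The \linkS4class{CohortManifest}, invisibly also written to
#'   \code{dir/manifest.json}.
#' @export
simulateCohort <- function(params, dir) {
  stopifnot(inherits(params, "SimulationParams"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("simulateCohort: cannot create ", dir)
  entries <- list()
  for (s in seq_len(params$nSubjects)) {
    for (state in fatigueStates()) {
      group <- simulateRecording(params, s, state)
      for (site in sensorSites()) {
        stub <- sprintf("S%02d_%s_%s", s, state, site)
        imu <- paste0(stub, "_imu.csv")
        emg <- paste0(stub, "_emg.csv")
        writeRecording(group[[site]], file.path(dir, imu),
                       file.path(dir, emg))
        entries[[length(entries) + 1L]] <- data.frame(
          subject = sprintf("S%02d", s), state = state, site = site,
          imu_path = imu, emg_path = emg, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- methods::new("CohortManifest",
    entries = do.call(rbind, entries),
    imuRate = IMU_RATE, emgRate = EMG_RATE,
    root = normalizePath(dir))
  writeManifest(manifest, file.path(dir, "manifest.json"))
  manifest
}

#' Simulate, preprocess and segment a cohort in memory
#'
#' Convenience wrapper running the full front half of the pipeline without
#' touching disk: simulate every subject-state group, condition it with
#' \code{\link{preprocessRecording}}, and assemble the z-scored
#' \linkS4class{SegmentSet}.
#'
#' @param params a \code{\link{simulationParams}}.
#' @param filters a \code{\link{filterSpec}}.
#' @param windowsPerRecording windows kept per recording.
#' @return A \linkS4class{SegmentSet} of
#'   \code{nSubjects * 2 * windowsPerRecording} segments.
#' @export
simulateSegmentSet <- function(params, filters = filterSpec(),
                               windowsPerRecording = 9) {
  recs <- list()
  for (s in seq_len(params$nSubjects)) {
    for (state in fatigueStates()) {
      group <- simulateRecording(params, s, state)
      recs[[length(recs) + 1L]] <- preprocessRecording(group, filters)
    }
  }
  assembleDataset(recs, windowsPerRecording = windowsPerRecording)
}

.groupJerkRMS <- function(group) {
  v <- unlist(lapply(c("TAL", "TAR", "RFL", "RFR"), function(site) {
    acc <- group[[site]]@acc
    acc[group[[site]]@accMask] <- NA
    j <- apply(acc, 2L, function(x) diff(x) * group[[site]]@imuRate)
    j[is.finite(j)]
  }))
  sqrt(mean(v^2))
}

.groupEmgEnvRMS <- function(group, sites = c("GLL", "GLR")) {
  vapply(sites, function(site) {
    e <- group[[site]]@emg
    e[group[[site]]@emgMask] <- NA
    e <- e[is.finite(e)]
    env <- movingAverage(abs(e), fs = group[[site]]@emgRate, windowMs = 100)
    sqrt(mean(env^2))
  }, numeric(1))
}

#' Realized fatigue effect sizes of a cohort
#'
#' Compares each subject's fatigued and non-fatigued recordings on three
#' summary statistics computed directly from the raw signals: RMS linear
#' jerk of the IMU limb sites (forward difference of acceleration), RMS of
#' the GL EMG envelope (rectified + 100 ms moving average), and a signed
#' left-right EMG asymmetry index \code{(L - R) / mean(L, R)} (positive =
#' left-dominant, the side the asymmetry gain acts on). The ratios
#' (fatigued / non-fatigued) show the effect sizes the generator actually
#' realized, next to the configured gains.
#'
#' @param cohort a \linkS4class{CohortManifest}, or a
#'   \code{\link{simulationParams}} (the cohort is then regenerated in
#'   memory).
#' @return data.frame with one row per subject: jerkRatio, emgRatio,
#'   asymmetryNonFatigued, asymmetryFatigued.
#' @export
effectReport <- function(cohort) {
  loadGroup <- if (inherits(cohort, "SimulationParams")) {
    subjects <- seq_len(cohort$nSubjects)
    function(s, state) simulateRecording(cohort, s, state)
  } else if (methods::is(cohort, "CohortManifest")) {
    g <- recordingGroups(cohort)
    subjects <- unique(g$subject)
    function(s, state) readRecordingGroup(cohort, s, state)
  } else stop("effectReport: need a CohortManifest or SimulationParams")
  rows <- lapply(subjects, function(s) {
    nf <- loadGroup(s, "non_fatigued")
    ft <- loadGroup(s, "fatigued")
    envNf <- .groupEmgEnvRMS(nf)
    envFt <- .groupEmgEnvRMS(ft)
    asym <- function(e) (e[["GLL"]] - e[["GLR"]]) / mean(e)
    data.frame(
      subject = nf[[1L]]@subjectId,
      jerkRatio = .groupJerkRMS(ft) / .groupJerkRMS(nf),
      emgRatio = mean(envFt) / mean(envNf),
      asymmetryNonFatigued = asym(envNf),
      asymmetryFatigued = asym(envFt),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
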