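#' @include AllClasses.R
NULL

# Delimited-text dialect: one CSV per (subject, state, site, modality) with a
# header row; IMU files carry time,ax,ay,az,gx,gy,gz and EMG files time,emg.
# Empty cells encode missing samples (sensor dropout) and map to the masks.
# Values are written with 17 significant digits so that a write/read round
# trip is bit-identical for finite doubles.

IMU_COLUMNS <- c("time", "ax", "ay", "az", "gx", "gy", "gz")
EMG_COLUMNS <- c("time", "emg")

.readSignalCSV <- function(path, expected) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, colClasses = "numeric",
                    check.names = FALSE),
    error = function(e) stop("malformed signal file ", path, ": ",
                             conditionMessage(e)))
  if (!identical(names(df), expected))
    stop(sprintf("format error in %s: expected columns [%s], found [%s]",
                 path, paste(expected, collapse = ","),
                 paste(names(df), collapse = ",")))
  df
}

.checkDeclaredRate <- function(time, rate, path) {
  # time column is authoritative for the file's rate; compare to the manifest
  if (length(time) < 2L) return(invisible(NULL))
  ok <- is.finite(time)
  dt <- stats::median(diff(time[ok]))
  if (!is.finite(dt) || dt <= 0 || abs(1 / dt - rate) / rate > 0.01)
    stop(sprintf("rate error in %s: time column implies %.2f Hz, manifest declares %g Hz",
                 path, if (is.finite(dt) && dt > 0) 1 / dt else NA_real_, rate))
  invisible(NULL)
}

#' Read one multi-rate sensor recording
#'
#' Reads the IMU (accelerometer + gyroscope) and EMG delimited-text files of
#' one (subject, state, site) triple and assembles a
#' \linkS4class{RawRecording}. Empty cells become entries of the missing
#' masks; the stored value at a masked index is \code{NA}. The time columns
#' are checked against the declared sampling rates (1 \% tolerance).
#'
#' @param imuPath,emgPath paths to the IMU and EMG CSV files.
#' @param subjectId,state,site recording metadata (see
#'   \code{\link{fatigueStates}}, \code{\link{sensorSites}}).
#' @param imuRate,emgRate declared sampling rates in Hz.
#' @return A \linkS4class{RawRecording}.
#' @seealso \code{\link{writeRecording}}, \code{\link{readManifest}}
#' @export
readRecording <- function(imuPath, emgPath, subjectId, state, site,
                          imuRate = 148, emgRate = 1259) {
  imu <- .readSignalCSV(imuPath, IMU_COLUMNS)
  emg <- .readSignalCSV(emgPath, EMG_COLUMNS)
  .checkDeclaredRate(imu$time, imuRate, imuPath)
  .checkDeclaredRate(emg$time, emgRate, emgPath)
  acc <- as.matrix(imu[, c("ax", "ay", "az")])
  gyro <- as.matrix(imu[, c("gx", "gy", "gz")])
  dimnames(acc) <- dimnames(gyro) <- NULL
  emgv <- emg$emg
  methods::new("RawRecording",
    subjectId = subjectId, state = state, site = site,
    acc = acc, gyro = gyro, emg = emgv,
    accMask = is.na(acc), gyroMask = is.na(gyro), emgMask = is.na(emgv),
    imuRate = imuRate, emgRate = emgRate)
}

.fmt <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write one recording back to delimited text
#'
#' Writes the IMU and EMG streams of a \linkS4class{RawRecording} as the same
#' two-file CSV dialect that \code{\link{readRecording}} reads. Masked samples
#' are written as empty cells; a round trip reproduces every finite value
#' bit-identically. Non-finite values outside the mask are refused.
#'
#' @param rec A \linkS4class{RawRecording}.
#' @param imuPath,emgPath output file paths (directories must exist).
#' @return Invisibly, the two paths.
#' @export
writeRecording <- function(rec, imuPath, emgPath) {
  methods::validObject(rec)
  nI <- nrow(rec@acc)
  timeI <- (seq_len(nI) - 1) / rec@imuRate
  acc <- rec@acc; acc[rec@accMask] <- NA
  gyro <- rec@gyro; gyro[rec@gyroMask] <- NA
  imu <- cbind(.fmt(timeI), .fmt(acc[, 1]), .fmt(acc[, 2]), .fmt(acc[, 3]),
               .fmt(gyro[, 1]), .fmt(gyro[, 2]), .fmt(gyro[, 3]))
  nE <- length(rec@emg)
  timeE <- (seq_len(nE) - 1) / rec@emgRate
  emgv <- rec@emg; emgv[rec@emgMask] <- NA
  emg <- cbind(.fmt(timeE), .fmt(emgv))
  .writeTable <- function(m, header, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(header, collapse = ","), con)
    writeLines(apply(m, 1L, paste, collapse = ","), con)
  }
  .writeTable(imu, IMU_COLUMNS, imuPath)
  .writeTable(emg, EMG_COLUMNS, emgPath)
  invisible(c(imu = imuPath, emg = emgPath))
}

#' Read and validate a cohort manifest
#'
#' The manifest is a JSON file declaring the cohort's sampling rates and one
#' entry per (subject, state, site) triple with the IMU and EMG file paths
#' (relative to the manifest's directory). Duplicate triples are an error;
#' (subject, state) groups that do not cover all six sensor sites are dropped
#' with a warning, so the returned manifest contains only complete recording
#' groups.
#'
#' @param path path to the manifest JSON.
#' @return A \linkS4class{CohortManifest}.
#' @export
readManifest <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L)
    stop("manifest error: missing or empty manifest file: ", path)
  m <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("manifest error: ",
                                         conditionMessage(e)))
  need <- c("imu_rate", "emg_rate", "entries")
  if (!all(need %in% names(m)))
    stop("manifest error: required fields: ", paste(need, collapse = ", "))
  entries <- as.data.frame(m$entries, stringsAsFactors = FALSE)
  cols <- c("subject", "state", "site", "imu_path", "emg_path")
  if (nrow(entries) == 0L || !all(cols %in% names(entries)))
    stop("manifest error: entries need columns ", paste(cols, collapse = ", "))
  entries <- entries[, cols]
  key <- with(entries, paste(subject, state, site))
  if (anyDuplicated(key))
    stop("manifest error: duplicate (subject, state, site) triples: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (!all(entries$state %in% fatigueStates()))
    stop("manifest error: unknown state labels: ",
         paste(setdiff(entries$state, fatigueStates()), collapse = ", "))
  if (!all(entries$site %in% sensorSites()))
    stop("manifest error: unknown sites: ",
         paste(setdiff(entries$site, sensorSites()), collapse = ", "))
  grpKey <- paste(entries$subject, entries$state, sep = "|")
  complete <- vapply(split(entries$site, grpKey),
                     function(s) setequal(s, sensorSites()), logical(1))
  if (any(!complete)) {
    warning("excluding incomplete recording groups (missing sites): ",
            paste(names(complete)[!complete], collapse = "; "))
    entries <- entries[grpKey %in% names(complete)[complete], , drop = FALSE]
  }
  if (nrow(entries) == 0L)
    stop("manifest error: no complete (subject, state) recording groups")
  rownames(entries) <- NULL
  methods::new("CohortManifest", entries = entries,
               imuRate = as.numeric(m$imu_rate),
               emgRate = as.numeric(m$emg_rate),
               root = normalizePath(dirname(path)))
}

#' Write a cohort manifest
#'
#' @param manifest A \linkS4class{CohortManifest}.
#' @param path output path for the manifest JSON.
#' @return Invisibly, \code{path}.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(
    list(imu_rate = manifest@imuRate, emg_rate = manifest@emgRate,
         entries = manifest@entries),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Recording groups of a manifest
#'
#' @param manifest A \linkS4class{CohortManifest}.
#' @return data.frame with one row per complete (subject, state) group.
#' @export
recordingGroups <- function(manifest) {
  g <- unique(manifest@entries[, c("subject", "state")])
  rownames(g) <- NULL
  g[order(g$subject, g$state), , drop = FALSE]
}

#' Read the six-site recording group of one subject-state
#'
#' @param manifest A \linkS4class{CohortManifest}.
#' @param subject,state the group to load.
#' @return Named list of six \linkS4class{RawRecording}s, in
#'   \code{sensorSites()} order.
#' @export
readRecordingGroup <- function(manifest, subject, state) {
  e <- manifest@entries
  e <- e[e$subject == subject & e$state == state, , drop = FALSE]
  if (nrow(e) != 6L)
    stop(sprintf("no complete group for subject %s, state %s", subject, state))
  e <- e[match(sensorSites(), e$site), , drop = FALSE]
  recs <- lapply(seq_len(nrow(e)), function(i) {
    readRecording(file.path(manifest@root, e$imu_path[i]),
                  file.path(manifest@root, e$emg_path[i]),
                  subjectId = subject, state = state, site = e$site[i],
                  imuRate = manifest@imuRate, emgRate = manifest@emgRate)
  })
  names(recs) <- sensorSites()
  recs
}
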