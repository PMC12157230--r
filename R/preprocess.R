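#' @include AllClasses.R
NULL

# Per-channel conditioning chain:
#   outlier mask -> gap interpolation -> zero-phase band-pass ->
#   (IMU) jerk + 100 ms smoothing | (EMG) rectify + 100 ms smoothing ->
#   band-limited resample to 148 Hz -> truncate to common length.
# Filtering happens at each channel's native rate (EMG at 1259 Hz, so the
# 20-500 Hz band is applied before the envelope is brought below the new
# Nyquist by smoothing + resampling).

#' Band-pass filter specifications per modality
#'
#' Default pass-bands: gyroscope 0.25-30 Hz, accelerometer 1-20 Hz,
#' EMG 20-500 Hz; 4th-order Butterworth applied forward-backward
#' (zero-phase, two passes).
#'
#' @param gyroBand,accBand,emgBand numeric length-2 vectors (Hz).
#' @param order Butterworth order of each pass.
#' @return List of class \code{"FilterSpec"}.
#' @export
filterSpec <- function(gyroBand = c(0.25, 30), accBand = c(1, 20),
                       emgBand = c(20, 500), order = 4L) {
  spec <- list(gyro = gyroBand, acc = accBand, emg = emgBand,
               order = as.integer(order))
  for (m in c("gyro", "acc", "emg")) {
    b <- spec[[m]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      stop("invalid band for ", m, ": need 0 < low < high")
  }
  class(spec) <- "FilterSpec"
  spec
}

#' Mask samples beyond k standard deviations
#'
#' Single-pass outlier detection: the mean and SD are computed once over the
#' unmasked samples, and every sample with \code{|x - mean| > k * SD} is added
#' to the missing mask. Values are left untouched (interpolation replaces
#' them later). A constant channel (SD = 0) passes through unchanged.
#'
#' @param x numeric vector.
#' @param mask logical vector, \code{TRUE} = already missing.
#' @param k SD multiplier (default 3).
#' @return List with \code{x} (unchanged) and the enlarged \code{mask}.
#' @export
removeOutliers <- function(x, mask = is.na(x), k = 3) {
  if (all(mask)) stop("removeOutliers: all samples are masked")
  good <- x[!mask]
  if (length(good) < 2L) return(list(x = x, mask = mask))
  mu <- mean(good)
  sd <- stats::sd(good)
  if (!is.finite(sd) || sd == 0) return(list(x = x, mask = mask))
  out <- !mask & abs(x - mu) > k * sd
  out[is.na(out)] <- FALSE
  list(x = x, mask = mask | out)
}

#' Fill masked samples by linear interpolation
#'
#' Interior gaps are linearly interpolated between the nearest unmasked
#' neighbours; leading/trailing gaps are filled by extending the nearest
#' unmasked value. Idempotent on its own output.
#'
#' @param x numeric vector.
#' @param mask logical vector, \code{TRUE} = missing.
#' @return Gap-free numeric vector of the same length.
#' @export
interpolateMissing <- function(x, mask = is.na(x)) {
  if (all(mask)) stop("interpolateMissing: fully masked series")
  if (!any(mask)) return(x)
  idx <- seq_along(x)
  stats::approx(idx[!mask], x[!mask], xout = idx, method = "linear",
                rule = 2)$y
}

.butterBand <- function(band, order, fs) {
  nyq <- fs / 2
  if (band[2] >= nyq)
    stop(sprintf("filter spec error: high edge %g Hz >= Nyquist %g Hz",
                 band[2], nyq))
  signal::butter(order, band / nyq, type = "pass")
}

#' Zero-phase Butterworth band-pass
#'
#' Designs a Butterworth band-pass of the given order and applies it
#' forward-backward (\code{signal::filtfilt}), giving zero phase shift and
#' preserving length.
#'
#' @param x numeric vector.
#' @param band numeric length-2 pass-band in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order per pass (default 4).
#' @return Filtered vector, same length as \code{x}.
#' @export
bandpassFilter <- function(x, band, fs, order = 4L) {
  bf <- .butterBand(band, order, fs)
  as.numeric(signal::filtfilt(bf, x))
}

#' Full-wave rectification
#'
#' @param x numeric vector (typically band-passed EMG).
#' @return \code{abs(x)}.
#' @export
rectifyEMG <- function(x) abs(x)

#' Centred moving-average smoothing
#'
#' Window length in samples is \code{round(windowMs/1000 * fs)}, forced odd
#' (+1 if even) so the window has an unambiguous centre. Edges are handled by
#' shrinking the window to the available samples, so output length equals
#' input length and a constant series is unchanged.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param windowMs window length in milliseconds (default 100).
#' @return Smoothed vector, same length.
#' @export
movingAverage <- function(x, fs, windowMs = 100) {
  w <- as.integer(round(windowMs / 1000 * fs))
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  if (w > n) stop(sprintf("movingAverage: window (%d) exceeds series length (%d)",
                          w, n))
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.forwardDiff <- function(m, fs) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2L) stop("jerk: need at least 2 frames")
  d <- (m[-1L, , drop = FALSE] - m[-n, , drop = FALSE]) * fs
  rbind(d, d[n - 1L, , drop = FALSE])  # replicate last to preserve length
}

#' Linear jerk from 3-axis acceleration
#'
#' Forward difference \code{(a(t+dt) - a(t)) / dt} with \code{dt = 1/fs}
#' (units m/s^3); the final frame is replicated from its predecessor so the
#' output has the same number of frames.
#'
#' @param acc numeric matrix, frames x 3 (m/s^2).
#' @param fs frame rate in Hz.
#' @return Matrix of the same shape.
#' @export
linearJerk <- function(acc, fs) .forwardDiff(acc, fs)

#' Angular jerk from 3-axis angular velocity
#'
#' Computed, like \code{\link{linearJerk}}, as the forward difference of the
#' gyroscope signal: \code{(w(t+dt) - w(t)) / dt}, i.e. the first derivative
#' of angular velocity (units rad/s^2). \code{order = 2} applies the
#' difference twice, yielding the second derivative of angular velocity for
#' users who want the rate of change of angular acceleration instead.
#'
#' @param gyro numeric matrix, frames x 3 (rad/s).
#' @param fs frame rate in Hz.
#' @param order 1 (default, first derivative) or 2.
#' @return Matrix of the same shape.
#' @export
angularJerk <- function(gyro, fs, order = 1L) {
  out <- .forwardDiff(gyro, fs)
  if (order == 2L) out <- .forwardDiff(out, fs)
  out
}

#' Band-limited resampling onto a target rate
#'
#' Identity when the rates match. Otherwise the signal is zero-phase low-pass
#' filtered at 90 \% of the target Nyquist (4th-order Butterworth, two-pass)
#' to prevent aliasing, then evaluated on the target time grid by linear
#' interpolation (negligible interpolation error: the anti-alias filter keeps
#' only content far below the input rate). Output length is
#' \code{round(n * fsOut / fsIn)}.
#'
#' @param x numeric vector.
#' @param fsIn,fsOut input/output rates in Hz.
#' @return Resampled vector.
#' @export
resampleSignal <- function(x, fsIn, fsOut = 148) {
  if (fsIn <= 0 || fsOut <= 0) stop("resampleSignal: rates must be positive")
  if (fsIn == fsOut) return(x)
  nOut <- as.integer(round(length(x) * fsOut / fsIn))
  if (fsOut < fsIn) {
    lp <- signal::butter(4, 0.9 * fsOut / fsIn, type = "low")
    x <- as.numeric(signal::filtfilt(lp, x))
  }
  tIn <- (seq_along(x) - 1) / fsIn
  tOut <- (seq_len(nOut) - 1) / fsOut
  stats::approx(tIn, x, xout = tOut, method = "linear", rule = 2)$y
}

.conditionChannel <- function(x, mask, band, fs, order, outlierK) {
  o <- removeOutliers(x, mask, k = outlierK)
  x <- interpolateMissing(o$x, o$mask)
  bandpassFilter(x, band, fs, order)
}

#' Condition one six-site recording group
#'
#' Applies the full conditioning chain to every channel of the six
#' \linkS4class{RawRecording}s of one subject-state and stacks the results
#' into a \linkS4class{ProcessedRecording} on the common 148 Hz grid.
#' Per channel, in order: (1) outlier masking (\eqn{\pm}\code{outlierK} SD),
#' (2) linear gap interpolation, (3) zero-phase band-pass at the native rate,
#' (4) IMU: jerk (forward difference) then 100 ms moving average;
#' EMG: rectification then 100 ms moving average (envelope),
#' (5) resampling to \code{targetRate}, (6) truncation of all channels to the
#' common minimum frame count.
#'
#' @param group named list of six \linkS4class{RawRecording}s (one per site,
#'   as returned by \code{\link{readRecordingGroup}} or
#'   \code{\link{simulateRecording}}).
#' @param filters a \code{\link{filterSpec}}.
#' @param targetRate common output frame rate (Hz).
#' @param windowMs smoothing window (ms).
#' @param outlierK outlier SD multiplier.
#' @param angularJerkOrder 1 (as-derived angular jerk, default) or 2.
#' @return A \linkS4class{ProcessedRecording} with 7 channels per site
#'   (\code{emg}, \code{linjerk.x/y/z}, \code{angjerk.x/y/z}).
#' @export
preprocessRecording <- function(group, filters = filterSpec(),
                                targetRate = 148, windowMs = 100,
                                outlierK = 3, angularJerkOrder = 1L) {
  if (!setequal(names(group), sensorSites()))
    stop("preprocessRecording: group must contain all six sites; missing: ",
         paste(setdiff(sensorSites(), names(group)), collapse = ", "))
  group <- group[sensorSites()]
  ref <- group[[1L]]
  cols <- list(); nms <- character(0)
  axes <- c("x", "y", "z")
  for (site in sensorSites()) {
    rec <- group[[site]]
    if (rec@site != site)
      stop("preprocessRecording: site mismatch in group entry ", site)
    fsI <- rec@imuRate; fsE <- rec@emgRate
    cond <- function(m, maskM, band) {
      vapply(1:3, function(j)
        .conditionChannel(m[, j], maskM[, j], band, fsI, filters$order,
                          outlierK),
        numeric(nrow(m)))
    }
    accF <- tryCatch(cond(rec@acc, rec@accMask, filters$acc),
                     error = function(e) stop("recording rejected (", site,
                                              " acc): ", conditionMessage(e)))
    gyroF <- tryCatch(cond(rec@gyro, rec@gyroMask, filters$gyro),
                      error = function(e) stop("recording rejected (", site,
                                               " gyro): ", conditionMessage(e)))
    lj <- linearJerk(accF, fsI)
    aj <- angularJerk(gyroF, fsI, order = angularJerkOrder)
    lj <- apply(lj, 2L, movingAverage, fs = fsI, windowMs = windowMs)
    aj <- apply(aj, 2L, movingAverage, fs = fsI, windowMs = windowMs)
    emgF <- tryCatch(
      .conditionChannel(rec@emg, rec@emgMask, filters$emg, fsE,
                        filters$order, outlierK),
      error = function(e) stop("recording rejected (", site, " emg): ",
                               conditionMessage(e)))
    env <- movingAverage(rectifyEMG(emgF), fs = fsE, windowMs = windowMs)
    envR <- resampleSignal(env, fsE, targetRate)
    ljR <- apply(lj, 2L, resampleSignal, fsIn = fsI, fsOut = targetRate)
    ajR <- apply(aj, 2L, resampleSignal, fsIn = fsI, fsOut = targetRate)
    cols <- c(cols, list(envR),
              lapply(1:3, function(j) ljR[, j]),
              lapply(1:3, function(j) ajR[, j]))
    nms <- c(nms, paste0(site, ".emg"),
             paste0(site, ".linjerk.", axes), paste0(site, ".angjerk.", axes))
  }
  nMin <- min(vapply(cols, length, integer(1)))
  data <- vapply(cols, function(v) v[seq_len(nMin)], numeric(nMin))
  colnames(data) <- NULL
  methods::new("ProcessedRecording",
    subjectId = ref@subjectId, state = ref@state,
    data = data, channelNames = nms, rate = targetRate)
}
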