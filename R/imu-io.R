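# Reading/writing the IMU CSV stream and window/orientation handling.

.CSV_HEADER <- c("time_s", "ax_g", "ay_g", "az_g", "wx_dps", "wy_dps",
                 "wz_dps", "gx_deg", "gy_deg", "gz_deg")

#' Read a heel-IMU recording from delimited text
#'
#' Reads the package's CSV dialect: comma-separated, UTF-8, '.' decimal,
#' header `time_s,ax_g,ay_g,az_g,wx_dps,wy_dps,wz_dps,gx_deg,gy_deg,gz_deg`
#' (units: g, deg/s, deg). Rows with unparsable numerics are rejected with
#' their line numbers. Irregular timestamps are tolerated as long as the
#' median inter-sample interval matches `1/sampleRate` within 10%; the
#' returned recording is indexed on the nominal rate.
#'
#' @param path Path to the CSV file.
#' @param sampleRate Nominal sampling frequency in Hz (default 50).
#' @param subjectId Subject label for the recording; defaults to the file
#'   name without extension.
#' @return An [ImuRecording-class].
#' @seealso [writeImuCsv()]
#' @export
readImuCsv <- function(path, sampleRate = 50, subjectId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (nrow(dt) == 0L) stop("empty IMU file: ", path)
  missing <- setdiff(.CSV_HEADER, names(dt))
  if (length(missing))
    stop("IMU file is missing column(s): ", paste(missing, collapse = ", "))
  dt <- dt[, .CSV_HEADER]
  num <- suppressWarnings(vapply(dt, as.numeric, numeric(nrow(dt))))
  if (nrow(dt) == 1L) num <- matrix(num, 1L, dimnames = list(NULL, names(dt)))
  bad <- which(rowSums(is.na(num)) > 0L)
  if (length(bad)) {
    # +1 for the header line
    stop("unparsable numeric value(s) on line(s): ",
         paste(head(bad + 1L, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  }
  tm <- num[, "time_s"]
  if (nrow(num) >= 2L) {
    dtmed <- median(diff(tm))
    if (!is.finite(dtmed) || abs(dtmed - 1 / sampleRate) > 0.1 / sampleRate)
      stop(sprintf(
        "median inter-sample interval %.4g s differs from 1/%g Hz by more than 10%%",
        dtmed, sampleRate))
  }
  mat <- num[, -1L, drop = FALSE]
  colnames(mat) <- imuChannels()
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  ImuRecording(mat, sampleRate = sampleRate, t0 = tm[1],
               subjectId = subjectId)
}

#' Write a heel-IMU recording as delimited text
#'
#' Writes the CSV dialect read by [readImuCsv()]. Values are written with
#' `%.17g`, enough digits for an exact double round trip. If the recording
#' carries ground-truth heel strikes, they can be written to a two-column
#' sidecar (`strike_index`, 1-based sample index, and `time_s`).
#'
#' @param recording An [ImuRecording-class].
#' @param path Output CSV path.
#' @param strikesPath Optional path for the ground-truth strike sidecar.
#' @return `path`, invisibly.
#' @export
writeImuCsv <- function(recording, path, strikesPath = NULL) {
  stopifnot(is(recording, "ImuRecording"))
  tm <- recording@t0 + (seq_len(nSamples(recording)) - 1L) /
    recording@sampleRate
  df <- data.frame(tm, imuData(recording))
  names(df) <- .CSV_HEADER
  for (j in seq_along(df)) df[[j]] <- sprintf("%.17g", df[[j]])
  data.table::fwrite(df, path, sep = ",", quote = FALSE)
  if (!is.null(strikesPath)) {
    idx <- trueStrikeIndices(recording)
    tms <- recording@t0 + (idx - 1L) / recording@sampleRate
    data.table::fwrite(data.frame(strike_index = idx,
                                  time_s = sprintf("%.17g", tms)),
                       strikesPath, sep = "\t", quote = FALSE)
  }
  invisible(path)
}

#' Extract an analysis window from a recording
#'
#' Returns the half-open sample range `[round(start*fs), round(end*fs))`
#' of the bout clock as a new recording; a 60-s window at 50 Hz has exactly
#' 3000 samples. The window must lie within the recording.
#'
#' @param recording An [ImuRecording-class].
#' @param spec A [WindowSpec-class] on the same bout clock.
#' @return An [ImuRecording-class] with `t0 = spec` start; metadata is
#'   carried over.
#' @examples
#' rec <- simulateBout(gaitSimConfig(durationMin = 1, seed = 1))
#' w <- extractWindow(rec, windowSpec("baseline", 0, 30))
#' nSamples(w)  # 1500
#' @export
extractWindow <- function(recording, spec) {
  stopifnot(is(recording, "ImuRecording"), is(spec, "WindowSpec"))
  fs <- recording@sampleRate
  n0 <- round((spec@start - recording@t0) * fs)
  n1 <- round((spec@end - recording@t0) * fs)
  if (n0 < 0 || n1 > nSamples(recording))
    stop(sprintf("window '%s' [%g, %g) s exceeds the recording extent",
                 spec@label, spec@start, spec@end))
  ImuRecording(imuData(recording)[(n0 + 1L):n1, , drop = FALSE],
               sampleRate = fs, t0 = spec@start,
               subjectId = recording@subjectId, meta = recording@meta)
}

#' Baseline orientation reference of a recording
#'
#' The average orientation over the first `span` seconds of the recording:
#' circular mean (atan2 of averaged sines/cosines) for the `gx` and `gz`
#' angles, which live on the full (-180, 180] circle, and the arithmetic
#' mean for `gy`, whose [-90, 90] range cannot wrap.
#'
#' @param recording An [ImuRecording-class].
#' @param span Averaging span in seconds (default 30, the first 30 s of
#'   walking).
#' @return Named numeric vector `c(gx=, gy=, gz=)` in degrees.
#' @export
orientationReference <- function(recording, span = 30) {
  n <- round(span * recording@sampleRate)
  if (n > nSamples(recording))
    stop("recording shorter than the baseline orientation span")
  d <- imuData(recording)[seq_len(n), , drop = FALSE]
  c(gx = circularMeanDeg(d[, "gx"]),
    gy = mean(d[, "gy"]),
    gz = circularMeanDeg(d[, "gz"]))
}

#' Re-express orientation angles relative to a reference
#'
#' Replaces `gx`, `gy`, `gz` by their (circular) difference from the given
#' reference orientation: `gx`/`gz` differences are wrapped to
#' (-180, 180], `gy` to [-90, 90]. Acceleration and angular-velocity
#' channels are unchanged.
#'
#' @param recording An [ImuRecording-class].
#' @param reference Named vector as returned by [orientationReference()].
#' @return An [ImuRecording-class].
#' @export
applyOrientationReference <- function(recording, reference) {
  d <- imuData(recording)
  d[, "gx"] <- wrapAngle180(d[, "gx"] - reference[["gx"]])
  d[, "gz"] <- wrapAngle180(d[, "gz"] - reference[["gz"]])
  d[, "gy"] <- foldAngle90(d[, "gy"] - reference[["gy"]])
  ImuRecording(d, sampleRate = recording@sampleRate, t0 = recording@t0,
               subjectId = recording@subjectId, meta = recording@meta)
}

#' Orientation angles relative to the initial walking baseline
#'
#' Convenience wrapper: computes the orientation reference from the first
#' `baselineSpan` seconds of the recording ([orientationReference()]) and
#' subtracts it ([applyOrientationReference()]), so the angle channels
#' describe the change in heel orientation from the start of the bout.
#'
#' @inheritParams orientationReference
#' @param baselineSpan Averaging span in seconds (default 30).
#' @return An [ImuRecording-class].
#' @export
relativeAngles <- function(recording, baselineSpan = 30) {
  applyOrientationReference(
    recording, orientationReference(recording, span = baselineSpan))
}
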