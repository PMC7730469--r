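#' ImuRecording: a uniformly sampled nine-channel heel-IMU time series
#'
#' Container for one IMU stream: a numeric matrix with one row per sample
#' and the fixed nine-channel column order `ax, ay, az` (acceleration, g),
#' `wx, wy, wz` (angular velocity, deg/s), `gx, gy, gz` (orientation
#' angles, deg). The device x/y/z axes are the medial-lateral,
#' anterior-posterior and vertical axes.
#'
#' @slot data Numeric matrix, samples x 9 channels, columns named as
#'   [imuChannels()].
#' @slot sampleRate Sampling frequency in Hz (scalar, > 0).
#' @slot t0 Time of the first sample in seconds (relative to bout start).
#' @slot subjectId Character label for the subject.
#' @slot meta Free-form list of metadata. Simulated recordings carry
#'   `meta$strikes`, the ground-truth heel-strike times in seconds on the
#'   bout clock.
#'
#' @seealso [ImuRecording()], [simulateBout()], [readImuCsv()]
#' @export
setClass("ImuRecording",
  representation(
    data      = "matrix",
    sampleRate = "numeric",
    t0        = "numeric",
    subjectId = "character",
    meta      = "list"
  )
)

setValidity("ImuRecording", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("'data' must be a numeric matrix")
  if (ncol(d) != 9L) return("'data' must have exactly 9 channel columns")
  if (!identical(colnames(d), imuChannels()))
    return(sprintf("channel columns must be, in order: %s",
                   paste(imuChannels(), collapse = ", ")))
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    return("'sampleRate' must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    return("'t0' must be a single finite number")
  TRUE
})

#' Construct an ImuRecording
#'
#' @param data Numeric matrix (samples x 9) with columns in the order of
#'   [imuChannels()]; column names are set from that order if absent.
#' @param sampleRate Sampling frequency in Hz.
#' @param t0 Time of the first sample in seconds. Default 0.
#' @param subjectId Subject label. Default `""`.
#' @param meta List of metadata. Default empty.
#' @return An [ImuRecording-class] object.
#' @examples
#' rec <- ImuRecording(matrix(0, 100, 9), sampleRate = 50)
#' nSamples(rec)
#' duration(rec)
#' @export
ImuRecording <- function(data, sampleRate, t0 = 0, subjectId = "",
                         meta = list()) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) colnames(data) <- imuChannels()
  storage.mode(data) <- "double"
  new("ImuRecording", data = data, sampleRate = as.numeric(sampleRate),
      t0 = as.numeric(t0), subjectId = as.character(subjectId), meta = meta)
}

#' WindowSpec: a labelled analysis window in bout time
#'
#' A half-open time interval `[start, end)` in seconds on the bout clock,
#' with one of the labels `baseline`, `min30`, `min60`. The three standard
#' analysis windows are one minute long each: the first minute of the bout
#' and the minutes ending at the 30th and 60th minute marks.
#'
#' @slot label One of `"baseline"`, `"min30"`, `"min60"`.
#' @slot start,end Window bounds in seconds, `end > start`.
#' @seealso [windowSpec()], [analysisWindows()], [extractWindow()]
#' @export
setClass("WindowSpec",
  representation(label = "character", start = "numeric", end = "numeric")
)

setValidity("WindowSpec", function(object) {
  if (!object@label %in% .WINDOW_LABELS)
    return(sprintf("label must be one of: %s",
                   paste(.WINDOW_LABELS, collapse = ", ")))
  if (object@start < 0 || object@end <= object@start)
    return("need 0 <= start < end")
  TRUE
})

#' @rdname WindowSpec-class
#' @param label Window label.
#' @param start,end Bounds in seconds.
#' @return A `WindowSpec`.
#' @export
windowSpec <- function(label, start, end) {
  new("WindowSpec", label = label, start = as.numeric(start),
      end = as.numeric(end))
}

#' The three standard analysis windows
#'
#' Returns the named list of the three one-minute analysis windows for a
#' bout: the baseline (first) minute and the minutes ending at the given
#' minute marks.
#'
#' @param minutes Length-3 numeric vector of minute marks; window `i` is
#'   `[(minutes[i]-1)*60, minutes[i]*60)` seconds. Default `c(1, 30, 60)`.
#' @return Named list of three [WindowSpec-class] objects
#'   (`baseline`, `min30`, `min60`).
#' @examples
#' analysisWindows()
#' analysisWindows(c(1, 3, 5))  # for a short 5-minute bout
#' @export
analysisWindows <- function(minutes = c(1, 30, 60)) {
  stopifnot(length(minutes) == 3L, all(diff(minutes) > 0), minutes[1] >= 1)
  out <- Map(function(lab, m) windowSpec(lab, (m - 1) * 60, m * 60),
             .WINDOW_LABELS, minutes)
  names(out) <- .WINDOW_LABELS
  out
}

#' FatigueEffect: a simulated time-progressive change on one channel
#'
#' Describes how "fatigue" alters one channel of the synthetic gait signal
#' over the bout. The multiplier ramps piecewise-linearly in time and is
#' held flat across each analysis window, so it equals exactly 1 throughout
#' the baseline minute, `multiplier30` throughout the 30th-minute window
#' and `multiplier60` throughout the 60th-minute window.
#'
#' Properties:
#' \describe{
#'   \item{`amplitude_scale`}{scales the harmonic amplitudes of the
#'     channel's cycle waveform (offset untouched).}
#'   \item{`offset_shift`}{scales the channel's constant offset.}
#'   \item{`cycle_variability_scale`}{scales the cycle-to-cycle lognormal
#'     amplitude variability of the channel.}
#' }
#'
#' @slot channel One of [imuChannels()].
#' @slot property One of `"amplitude_scale"`, `"offset_shift"`,
#'   `"cycle_variability_scale"`.
#' @slot multiplier30,multiplier60 Positive multipliers attained at the
#'   30th- and 60th-minute windows (baseline is implicitly 1).
#' @seealso [fatigueEffect()], [gaitSimConfig()]
#' @export
setClass("FatigueEffect",
  representation(channel = "character", property = "character",
                 multiplier30 = "numeric", multiplier60 = "numeric")
)

.EFFECT_PROPERTIES <- c("amplitude_scale", "offset_shift",
                        "cycle_variability_scale")

setValidity("FatigueEffect", function(object) {
  if (!object@channel %in% imuChannels())
    return("unknown channel")
  if (!object@property %in% .EFFECT_PROPERTIES)
    return(sprintf("property must be one of: %s",
                   paste(.EFFECT_PROPERTIES, collapse = ", ")))
  if (object@multiplier30 <= 0 || object@multiplier60 <= 0)
    return("multipliers must be > 0")
  TRUE
})

#' @rdname FatigueEffect-class
#' @param channel,property,multiplier30,multiplier60 See slots.
#' @return A `FatigueEffect`.
#' @examples
#' fatigueEffect("gz", "amplitude_scale", multiplier30 = 1.2,
#'               multiplier60 = 1.4)
#' @export
fatigueEffect <- function(channel, property, multiplier30 = 1,
                          multiplier60 = 1) {
  new("FatigueEffect", channel = channel, property = property,
      multiplier30 = as.numeric(multiplier30),
      multiplier60 = as.numeric(multiplier60))
}

#' GaitSimConfig: configuration of the synthetic-gait simulator
#'
#' Describes one simulated treadmill brisk-walking bout. Each gait cycle is
#' a sum of harmonics of the cycle frequency per channel; cycle durations
#' jitter around `1/cadence` with a lognormal multiplier; per-cycle
#' amplitudes jitter with a mean-one lognormal multiplier; white Gaussian
#' sensor noise is added per channel; fatigue effects modify the per-cycle
#' template parameters on a time ramp anchored at the analysis windows.
#'
#' @slot sampleRate Hz, default 50.
#' @slot duration Bout duration in seconds (constructor takes minutes).
#' @slot cadence Stride (gait-cycle) frequency in Hz.
#' @slot cadenceJitterCv Coefficient of variation of the per-cycle duration
#'   multiplier (lognormal, mean 1).
#' @slot ampCv Coefficient of variation of the per-cycle, per-channel
#'   amplitude multiplier (lognormal, mean 1).
#' @slot templates Named list (one per channel) of
#'   `list(offset=, amp=, phase=)`: constant offset in channel units and
#'   harmonic amplitudes/phases; harmonic `k` contributes
#'   `amp[k] * cos(2*pi*k*phase_in_cycle + phase[k])`.
#' @slot noiseSd Named numeric vector of per-channel additive noise SDs.
#' @slot effects List of [FatigueEffect-class] objects.
#' @slot effectTimes Times (s) at which effect multipliers reach their
#'   30th- and 60th-minute targets; default `c(1800, 3600)`.
#' @slot seed Integer RNG seed; identical seeds give identical recordings.
#' @seealso [gaitSimConfig()], [simulateBout()]
#' @export
setClass("GaitSimConfig",
  representation(
    sampleRate = "numeric", duration = "numeric", cadence = "numeric",
    cadenceJitterCv = "numeric", ampCv = "numeric", templates = "list",
    noiseSd = "numeric", effects = "list", effectTimes = "numeric",
    seed = "integer"
  )
)

setValidity("GaitSimConfig", function(object) {
  if (object@sampleRate <= 0) return("sampleRate must be > 0")
  if (object@duration <= 0) return("duration must be > 0")
  if (object@cadence <= 0) return("cadence must be > 0")
  if (object@cadenceJitterCv < 0) return("cadenceJitterCv must be >= 0")
  if (object@ampCv < 0) return("ampCv must be >= 0")
  if (!identical(sort(names(object@templates)), sort(imuChannels())))
    return("templates must be a named list covering all nine channels")
  if (!identical(sort(names(object@noiseSd)), sort(imuChannels())))
    return("noiseSd must be a named vector covering all nine channels")
  if (any(object@noiseSd < 0)) return("noiseSd must be >= 0")
  if (length(object@effectTimes) != 2L ||
      object@effectTimes[1] >= object@effectTimes[2])
    return("effectTimes must be two increasing times")
  for (e in object@effects)
    if (!is(e, "FatigueEffect")) return("effects must be FatigueEffect objects")
  TRUE
})

#' Default per-channel cycle waveform templates
#'
#' Harmonic templates emulating heel kinematics during elderly brisk
#' treadmill walking (~3.9 km/h, stride frequency ~1 Hz): a dominant sharp
#' medial-lateral angular-velocity (`wx`) spike at heel strike (all
#' harmonics in phase at cycle phase 0), gravity offset on the vertical
#' accelerometer (`az`), and asymmetric waveforms on every channel - real
#' gait waveforms are skewed, and the within-cycle sample skewness of each
#' template is bounded away from zero (a property the baseline-ratio
#' normalization depends on; see the package vignette).
#'
#' @return Named list of `list(offset, amp, phase)` per channel.
#' @export
defaultChannelTemplates <- function() {
  list(
    ax = list(offset = 0.05, amp = c(0.30, 0.15, 0.08),
              phase = c(pi / 3, -pi / 4, pi / 6)),
    ay = list(offset = 0.10, amp = c(0.55, 0.25, 0.10),
              phase = c(-pi / 2, pi / 5, -pi / 3)),
    az = list(offset = 1.00, amp = c(0.90, 0.45, 0.20),
              phase = c(0.7, -0.9, 1.3)),
    wx = list(offset = 0, amp = c(180, 120, 70, 35),
              phase = c(0, 0, 0, 0)),
    wy = list(offset = 0, amp = c(90, 45, 20),
              phase = c(-1.1, 0.6, -0.4)),
    wz = list(offset = 0, amp = c(70, 35, 15),
              phase = c(2.0, -0.7, 0.9)),
    gx = list(offset = 0, amp = c(16, 6, 3),
              phase = c(-pi / 2, 0.8, -0.3)),
    gy = list(offset = 0, amp = c(10, 4, 2),
              phase = c(-pi / 2, 0.5, 1.0)),
    gz = list(offset = 0, amp = c(8, 3, 1.5),
              phase = c(-pi / 2, 0.7, -0.6))
  )
}

#' Default per-channel sensor-noise standard deviations
#'
#' Additive white-noise scales in channel units: 0.02 g on accelerations,
#' 3 deg/s on angular velocities, 0.5 deg on orientation angles.
#'
#' @return Named numeric vector over [imuChannels()].
#' @export
defaultNoiseSd <- function() {
  c(ax = 0.02, ay = 0.02, az = 0.02,
    wx = 3, wy = 3, wz = 3,
    gx = 0.5, gy = 0.5, gz = 0.5)
}

#' @rdname GaitSimConfig-class
#' @param durationMin Bout duration in minutes (default 60).
#' @param sampleRate,cadence,cadenceJitterCv,ampCv,templates,noiseSd,effects
#'   See slots.
#' @param effectTimesMin Minute marks of the two effect anchors
#'   (default `c(30, 60)`).
#' @param seed Integer seed.
#' @return A `GaitSimConfig`.
#' @examples
#' cfg <- gaitSimConfig(durationMin = 2, seed = 7)
#' rec <- simulateBout(cfg)
#' @export
gaitSimConfig <- function(durationMin = 60, sampleRate = 50, cadence = 1.0,
                          cadenceJitterCv = 0.03, ampCv = 0.05,
                          templates = defaultChannelTemplates(),
                          noiseSd = defaultNoiseSd(), effects = list(),
                          effectTimesMin = c(30, 60), seed = 1L) {
  new("GaitSimConfig", sampleRate = as.numeric(sampleRate),
      duration = as.numeric(durationMin) * 60, cadence = as.numeric(cadence),
      cadenceJitterCv = as.numeric(cadenceJitterCv), ampCv = as.numeric(ampCv),
      templates = templates[imuChannels()],
      noiseSd = noiseSd[imuChannels()], effects = effects,
      effectTimes = as.numeric(effectTimesMin) * 60, seed = as.integer(seed))
}

#' CycleFeatures: per-cycle signal statistics for one analysis window
#'
#' Values of the ten statistics ([gaitFeatures()]) for each of the nine
#' channels and each complete gait cycle of one window, stored as a
#' 3-dimensional array `[channel, feature, cycle]`.
#'
#' @slot windowLabel The window this matrix belongs to.
#' @slot values Numeric array `9 x 10 x nCycles` with dimnames
#'   (channel, feature, cycle).
#' @seealso [perCycleFeatures()], [windowMean()]
#' @export
setClass("CycleFeatures",
  representation(windowLabel = "character", values = "array")
)

setValidity("CycleFeatures", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || d[1] != 9L || d[2] != 10L)
    return("values must be a 9 x 10 x nCycles array")
  if (!identical(dimnames(object@values)[[1]], imuChannels()) ||
      !identical(dimnames(object@values)[[2]], gaitFeatures()))
    return("dimnames must be (imuChannels, gaitFeatures, .)")
  TRUE
})

#' CohortTable: subject x window blocks of normalized feature ratios
#'
#' For each of the 90 (channel, feature) blocks, a `subjects x 3` matrix of
#' baseline-normalized ratios (columns baseline, min30, min60). The
#' baseline column is identically 1 by construction. Cells flagged during
#' normalization (zero or missing baseline aggregate, empty window) are NA
#' and excluded listwise per block by [runBattery()].
#'
#' @slot data Numeric array `nSubjects x 3 x 90` with dimnames
#'   (subject, window, block); block names are `"<channel>.<feature>"`.
#' @slot log Character vector of data-quality notes accumulated upstream.
#' @seealso [buildCohortTable()], [runBattery()]
#' @export
setClass("CohortTable",
  representation(data = "array", log = "character")
)

setValidity("CohortTable", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || d[2] != 3L || d[3] != 90L)
    return("data must be nSubjects x 3 windows x 90 blocks")
  if (!identical(dimnames(object@data)[[2]], .WINDOW_LABELS))
    return("window dimension must be baseline, min30, min60")
  TRUE
})

#' StatReport: results of the repeated-measures nonparametric battery
#'
#' Friedman omnibus results for every (channel, feature) block, plus the
#' three Wilcoxon signed-rank contrasts (baseline-min30, baseline-min60,
#' min30-min60) with Bonferroni-adjusted p-values for blocks whose omnibus
#' p fell below `alpha`.
#'
#' @slot friedman data.frame: channel, feature, n, statistic, p.value,
#'   significant.
#' @slot posthoc data.frame: channel, feature, contrast, p.value,
#'   p.adjusted, significant, n.zero.dropped, degenerate.
#' @slot alpha Family significance level for the omnibus (default 0.05).
#' @slot posthocAlpha Corrected pairwise level, `alpha/3` (~0.017).
#' @slot nSubjects Number of subjects in the cohort.
#' @slot log Character vector of notes (exclusions, degeneracies).
#' @seealso [runBattery()], [friedmanWideTable()], [posthocTable()]
#' @export
setClass("StatReport",
  representation(friedman = "data.frame", posthoc = "data.frame",
                 alpha = "numeric", posthocAlpha = "numeric",
                 nSubjects = "integer", log = "character")
)
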