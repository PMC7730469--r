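#' Accessors for heelgait objects
#'
#' @param object An object of one of the package's S4 classes.
#' @return `imuData()` the samples-x-9 channel matrix; `sampleRate()` the
#'   sampling frequency (Hz); `nSamples()` the number of samples;
#'   `duration()` the recorded span in seconds; `subjectId()` the subject
#'   label; `startTime()` the bout-clock time of the first sample;
#'   `nCycles()` the number of gait cycles; `windowLabel()` the analysis
#'   window label; `featureValues()` the per-cycle feature array;
#'   `nSubjects()` the cohort size.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imuData", function(object) standardGeneric("imuData"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("nCycles", function(object) standardGeneric("nCycles"))
#' @rdname accessors
#' @export
setGeneric("windowLabel", function(object) standardGeneric("windowLabel"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setMethod("imuData", "ImuRecording", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("sampleRate", "ImuRecording", function(object) object@sampleRate)
#' @rdname accessors
#' @export
setMethod("nSamples", "ImuRecording", function(object) nrow(object@data))
#' @rdname accessors
#' @export
setMethod("duration", "ImuRecording",
          function(object) nrow(object@data) / object@sampleRate)
#' @rdname accessors
#' @export
setMethod("subjectId", "ImuRecording", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("startTime", "ImuRecording", function(object) object@t0)

#' @rdname accessors
#' @export
setMethod("nCycles", "CycleFeatures", function(object) dim(object@values)[3])
#' @rdname accessors
#' @export
setMethod("windowLabel", "CycleFeatures", function(object) object@windowLabel)
#' @rdname accessors
#' @export
setMethod("featureValues", "CycleFeatures", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("nSubjects", "CohortTable", function(object) dim(object@data)[1])
#' @rdname accessors
#' @export
setMethod("nSubjects", "StatReport", function(object) object@nSubjects)

setMethod("show", "ImuRecording", function(object) {
  cat(sprintf(
    "ImuRecording: %d samples x 9 channels @ %g Hz (%.1f s), t0 = %g s\n",
    nSamples(object), sampleRate(object), duration(object), object@t0))
  if (nzchar(object@subjectId))
    cat(sprintf("  subject: %s\n", object@subjectId))
  if (!is.null(object@meta$strikes))
    cat(sprintf("  ground-truth heel strikes: %d\n",
                length(object@meta$strikes)))
})

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec '%s': [%g, %g) s\n",
              object@label, object@start, object@end))
})

setMethod("show", "GaitSimConfig", function(object) {
  cat(sprintf(
    "GaitSimConfig: %.1f min @ %g Hz, cadence %g Hz (jitter cv %g, amp cv %g), seed %d\n",
    object@duration / 60, object@sampleRate, object@cadence,
    object@cadenceJitterCv, object@ampCv, object@seed))
  if (length(object@effects)) {
    cat(sprintf("  %d fatigue effect(s):\n", length(object@effects)))
    for (e in object@effects)
      cat(sprintf("    %s %s: x%g @30min, x%g @60min\n", e@channel,
                  e@property, e@multiplier30, e@multiplier60))
  }
})

setMethod("show", "CycleFeatures", function(object) {
  cat(sprintf("CycleFeatures '%s': 9 channels x 10 features x %d cycles\n",
              object@windowLabel, nCycles(object)))
})

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: %d subjects x 3 windows x 90 blocks (%d NA cells)\n",
              nSubjects(object), sum(is.na(object@data))))
})

setMethod("show", "StatReport", function(object) {
  sig <- sum(object@friedman$significant, na.rm = TRUE)
  cat(sprintf(
    "StatReport: %d blocks, %d subjects; %d significant at alpha = %g\n",
    nrow(object@friedman), object@nSubjects, sig, object@alpha))
  if (nrow(object@posthoc)) {
    starred <- sum(object@posthoc$significant, na.rm = TRUE)
    cat(sprintf("  post hoc: %d contrasts, %d below adjusted alpha = %.3f\n",
                nrow(object@posthoc), starred, object@posthocAlpha))
  }
})
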