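# End-to-end orchestration: simulate/read -> orientation baseline ->
# window -> segment -> featurize -> normalize -> battery.

#' Analyse the three windows of one subject
#'
#' Given the three window recordings of one bout (simulated via
#' [simulateWindows()] or extracted from a full recording), subtracts the
#' baseline orientation (circular mean of the first `orientationSpan`
#' seconds of the baseline window), segments each window into complete
#' gait cycles, computes per-cycle features, averages within windows and
#' normalizes to baseline.
#'
#' A window with no complete cycles flags the subject-window: its ratios
#' are NA in the result (with a note) and the subject is excluded listwise
#' per block downstream.
#'
#' @param windows Named list of three [ImuRecording-class] objects
#'   (`baseline`, `min30`, `min60`).
#' @param minCycle,maxCycle Cycle duration gates in seconds (see
#'   [segmentCycles()]).
#' @param orientationSpan Baseline-orientation span in seconds
#'   (default 30).
#' @return List with `table` (long data.frame from
#'   [normalizeToBaseline()], or with NA values if the baseline window is
#'   empty), `cycleCounts` (named integer vector), `subject`.
#' @export
analyzeWindows <- function(windows, minCycle = 0.6, maxCycle = 2.5,
                           orientationSpan = 30) {
  stopifnot(identical(sort(names(windows)), sort(.WINDOW_LABELS)))
  ref <- orientationReference(windows$baseline, span = orientationSpan)
  prepared <- lapply(windows, applyOrientationReference, reference = ref)
  analyzeWindowsPrepared(prepared, minCycle = minCycle, maxCycle = maxCycle)
}

#' Analyse one full recording
#'
#' Full-recording variant of [analyzeWindows()]: computes the orientation
#' baseline from the first `orientationSpan` seconds of the bout, then
#' extracts the three analysis windows and proceeds identically.
#'
#' @param recording A full-bout [ImuRecording-class].
#' @param windows Named list of three [WindowSpec-class] (default
#'   [analysisWindows()]).
#' @inheritParams analyzeWindows
#' @return As [analyzeWindows()].
#' @export
analyzeRecording <- function(recording, windows = analysisWindows(),
                             minCycle = 0.6, maxCycle = 2.5,
                             orientationSpan = 30) {
  rec <- relativeAngles(recording, baselineSpan = orientationSpan)
  wrecs <- lapply(windows, function(w) extractWindow(rec, w))
  names(wrecs) <- vapply(windows, function(w) w@label, character(1))
  # angles are already baseline-relative; a zero reference is a no-op
  out <- analyzeWindowsPrepared(wrecs, minCycle = minCycle,
                                maxCycle = maxCycle)
  out
}

# analyzeWindows() without the orientation step (angles already relative)
analyzeWindowsPrepared <- function(windows, minCycle = 0.6, maxCycle = 2.5) {
  subject <- subjectId(windows$baseline)
  means <- list()
  counts <- integer(0)
  for (w in .WINDOW_LABELS) {
    cyc <- segmentCycles(windows[[w]], minCycle = minCycle,
                         maxCycle = maxCycle)
    counts[w] <- nrow(cyc)
    cf <- perCycleFeatures(windows[[w]], cyc, label = w)
    means[[w]] <- if (nrow(cyc) > 0L) windowMean(cf) else NULL
  }
  if (any(counts == 0L)) {
    message("subject ", subject, ": window(s) without complete cycles: ",
            paste(names(counts)[counts == 0L], collapse = ", "))
    na <- matrix(NA_real_, 9L, 10L,
                 dimnames = list(imuChannels(), gaitFeatures()))
    for (w in .WINDOW_LABELS) if (is.null(means[[w]])) means[[w]] <- na
  }
  if (all(counts > 0L)) {
    tbl <- normalizeToBaseline(means, subject = subject)
  } else {
    base <- means$baseline
    tbl <- do.call(rbind, lapply(.WINDOW_LABELS, function(w) {
      r <- means[[w]] / base
      if (w == "baseline") r[is.finite(r)] <- 1
      data.frame(subject = subject, window = w,
                 channel = rep(imuChannels(), times = 10L),
                 feature = rep(gaitFeatures(), each = 9L),
                 value = as.vector(r))
    }))
  }
  list(table = tbl, cycleCounts = counts, subject = subject)
}

#' Run the whole pipeline on a simulated or recorded cohort
#'
#' Orchestrates simulate/read -> orientation baseline -> window -> segment
#' -> featurize -> normalize -> battery as one reproducible, seeded run.
#'
#' In `simulate` mode, `n` subjects are generated from `simConfig` (only
#' the analysis windows are synthesized; see [simulateWindows()]). In
#' `read` mode, `paths` names one CSV per subject ([readImuCsv()]) and the
#' three windows are taken at `windowMinutes`.
#'
#' @param mode `"simulate"` or `"read"`.
#' @param simConfig A [GaitSimConfig-class] (simulate mode).
#' @param n Number of simulated subjects (default 18).
#' @param paths Character vector of CSV paths (read mode).
#' @param seed Master seed for cohort generation (default: the config
#'   seed).
#' @param windowMinutes Minute marks of the three analysis windows
#'   (default `c(1, 30, 60)`).
#' @param minCycle,maxCycle Segmentation gates in seconds.
#' @param alpha Omnibus significance level.
#' @param sampleRate Nominal rate for read mode (Hz).
#' @param outDir Optional output directory; if given, the two report
#'   tables ([writeStatReport()]), the per-subject normalized feature
#'   table (`normalized_features.tsv`) and a JSON run manifest are
#'   written there.
#' @return List with `report` ([StatReport-class]), `cohort`
#'   ([CohortTable-class]), `features` (long data.frame over all
#'   subjects), `cycleCounts` (subjects x windows matrix), `manifest`
#'   (list).
#' @examples
#' \donttest{
#' cfg <- gaitSimConfig(durationMin = 5, effectTimesMin = c(3, 5), seed = 1)
#' run <- runPipeline("simulate", simConfig = cfg, n = 6,
#'                    windowMinutes = c(1, 3, 5))
#' run$report
#' }
#' @export
runPipeline <- function(mode = c("simulate", "read"), simConfig = NULL,
                        n = 18L, paths = NULL, seed = NULL,
                        windowMinutes = c(1, 30, 60), minCycle = 0.6,
                        maxCycle = 2.5, alpha = 0.05, sampleRate = 50,
                        outDir = NULL) {
  mode <- match.arg(mode)
  windows <- analysisWindows(windowMinutes)
  if (mode == "simulate") {
    if (is.null(simConfig)) stop("simulate mode needs 'simConfig'")
    if (is.null(seed)) seed <- simConfig@seed
    cohortRecs <- simulateCohort(simConfig, n = n, seed = seed,
                                 windows = windows)
    analyses <- lapply(cohortRecs, analyzeWindows, minCycle = minCycle,
                       maxCycle = maxCycle)
  } else {
    if (is.null(paths) || !length(paths)) stop("read mode needs 'paths'")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    analyses <- lapply(paths, function(p) {
      analyzeRecording(readImuCsv(p, sampleRate = sampleRate),
                       windows = windows, minCycle = minCycle,
                       maxCycle = maxCycle)
    })
  }
  tables <- lapply(analyses, `[[`, "table")
  counts <- do.call(rbind, lapply(analyses, `[[`, "cycleCounts"))
  rownames(counts) <- vapply(analyses, `[[`, character(1), "subject")
  usable <- vapply(tables, function(t) !all(is.na(t$value)), logical(1))
  if (sum(usable) < 2L)
    stop("fewer than 2 subjects survive exclusions; cannot run the battery")
  cohort <- buildCohortTable(tables)
  report <- runBattery(cohort, alpha = alpha)
  features <- do.call(rbind, tables)
  manifest <- list(
    mode = mode, nSubjects = length(tables), seed = seed,
    windowMinutes = windowMinutes, minCycle = minCycle,
    maxCycle = maxCycle, alpha = alpha,
    cycleCounts = as.data.frame(counts),
    exclusions = report@log,
    packageVersion = as.character(utils::packageVersion("heelgait"))
  )
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeStatReport(report, outDir)
    data.table::fwrite(features,
                       file.path(outDir, "normalized_features.tsv"),
                       sep = "\t")
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(report = report, cohort = cohort, features = features,
       cycleCounts = counts, manifest = manifest)
}

#' Read a pipeline run configuration from YAML
#'
#' Structured-text configuration for [runPipeline()]. Recognized top-level
#' keys mirror the function arguments (`mode`, `subjects`, `paths`, `seed`,
#' `window_minutes`, `min_cycle`, `max_cycle`, `alpha`, `sample_rate`);
#' a `sim` block configures the simulator (`duration_min`, `cadence`,
#' `cadence_jitter_cv`, `amp_cv`, `seed`, `effect_times_min`, and an
#' `effects` list of `{channel, property, multiplier30, multiplier60}`).
#'
#' @param path YAML file path.
#' @return List of arguments suitable for `do.call(runPipeline, ...)`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("mode", "paths", "seed", "alpha")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$subjects)) args$n <- y$subjects
  if (!is.null(y$window_minutes)) args$windowMinutes <- y$window_minutes
  if (!is.null(y$min_cycle)) args$minCycle <- y$min_cycle
  if (!is.null(y$max_cycle)) args$maxCycle <- y$max_cycle
  if (!is.null(y$sample_rate)) args$sampleRate <- y$sample_rate
  if (!is.null(y$sim)) {
    s <- y$sim
    effects <- lapply(s$effects, function(e) {
      fatigueEffect(e$channel, e$property,
                    multiplier30 = if (is.null(e$multiplier30)) 1
                                   else e$multiplier30,
                    multiplier60 = if (is.null(e$multiplier60)) 1
                                   else e$multiplier60)
    })
    args$simConfig <- gaitSimConfig(
      durationMin = if (is.null(s$duration_min)) 60 else s$duration_min,
      sampleRate = if (is.null(s$sample_rate)) 50 else s$sample_rate,
      cadence = if (is.null(s$cadence)) 1.0 else s$cadence,
      cadenceJitterCv = if (is.null(s$cadence_jitter_cv)) 0.03
                        else s$cadence_jitter_cv,
      ampCv = if (is.null(s$amp_cv)) 0.05 else s$amp_cv,
      effects = effects,
      effectTimesMin = if (is.null(s$effect_times_min)) c(30, 60)
                       else s$effect_times_min,
      seed = if (is.null(s$seed)) 1L else s$seed
    )
  }
  args
}
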