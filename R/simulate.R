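# Synthetic heel-IMU gait simulator.
#
# A bout is synthesized cycle by cycle: heel-strike times are laid down
# first (jittered cycle durations), then every sample inside a cycle is the
# channel's harmonic template evaluated at the within-cycle phase, scaled by
# per-cycle multipliers (lognormal variability and time-ramped fatigue
# effects), plus white sensor noise. Because strike times are planned before
# any sample is drawn, the true heel-strike indices are known exactly, and
# the three analysis windows can be synthesized in isolation with samples
# bit-identical to the full bout (per-cycle noise sub-seeds).

# fatigue multiplier ramp: 1 across the baseline minute, linear rise,
# plateau m30 across [eT1-60, eT1], linear rise, plateau m60 from eT2-60 on
.rampValue <- function(t, m30, m60, effectTimes) {
  a <- effectTimes[1] - 60
  b <- effectTimes[1]
  cc <- effectTimes[2] - 60
  out <- numeric(length(t))
  out[t <= 60] <- 1
  i <- t > 60 & t < a
  out[i] <- 1 + (m30 - 1) * (t[i] - 60) / (a - 60)
  i <- t >= a & t <= b
  out[i] <- m30
  i <- t > b & t < cc
  out[i] <- m30 + (m60 - m30) * (t[i] - b) / (cc - b)
  out[t >= cc] <- m60
  out
}

# first sample index (0-based) of each cycle, consistent with the
# findInterval() assignment n belongs to cycle i iff n/fs >= strikes[i]
.cycleFirstSample <- function(strikes, fs) {
  n <- ceiling(strikes * fs - 1e-9)
  bad <- (n - 1) / fs >= strikes
  n[bad] <- n[bad] - 1L
  bad <- n / fs < strikes
  n[bad] <- n[bad] + 1L
  as.integer(n)
}

# deterministic per-bout plan: strike times, per-cycle multipliers and
# noise sub-seeds, all drawn from the config seed in a fixed order
.simPlan <- function(cfg) {
  fs <- cfg@sampleRate
  dur <- cfg@duration
  meanT <- 1 / cfg@cadence
  chans <- imuChannels()
  withr::with_seed(cfg@seed, {
    # the recording starts at a uniformly random phase of the gait cycle
    # (data capture is not synchronized to heel strikes), so every analysis
    # window is cut at a random phase and the three windows are
    # statistically exchangeable under the null
    u <- runif(1)
    cv <- cfg@cadenceJitterCv
    durs <- numeric(0)
    total <- 0
    repeat {
      k <- max(16L, ceiling((dur + meanT - total) * cfg@cadence * 1.2))
      add <- if (cv > 0) {
        sdlog <- sqrt(log1p(cv^2))
        meanT * rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        rep(meanT, k)
      }
      durs <- c(durs, add)
      total <- total + sum(add)
      if (total - u * durs[1] >= dur) break
    }
    # first strike just before t = 0; the head segment [0, strikes[2]) is a
    # partial cycle
    strikes <- c(0, cumsum(durs)) - u * durs[1]
    strikes <- strikes[seq_len(which(strikes >= dur)[1])]
    nCyc <- length(strikes) - 1L
    durs <- diff(strikes)

    z <- matrix(rnorm(nCyc * 9L), nCyc, 9L, dimnames = list(NULL, chans))
    noiseSeeds <- sample.int(.Machine$integer.max - 1L, nCyc)

    ampMul <- matrix(1, nCyc, 9L, dimnames = list(NULL, chans))
    offMul <- ampMul
    varMul <- ampMul
    tStart <- strikes[seq_len(nCyc)]
    for (e in cfg@effects) {
      m <- .rampValue(tStart, e@multiplier30, e@multiplier60, cfg@effectTimes)
      switch(e@property,
        amplitude_scale = {
          ampMul[, e@channel] <- ampMul[, e@channel] * m
        },
        offset_shift = {
          offMul[, e@channel] <- offMul[, e@channel] * m
        },
        cycle_variability_scale = {
          varMul[, e@channel] <- varMul[, e@channel] * m
        }
      )
    }
    # mean-one lognormal per-cycle amplitude variability
    s <- cfg@ampCv * varMul
    cycAmp <- ampMul * exp(s * z - s^2 / 2)

    list(strikes = strikes, durs = durs, nCyc = nCyc,
         firstSample = .cycleFirstSample(strikes, fs),
         cycAmp = cycAmp, offMul = offMul, noiseSeeds = noiseSeeds)
  })
}

# synthesize global samples [n0, n1) (0-based) from a plan
.synthRange <- function(cfg, plan, n0, n1) {
  fs <- cfg@sampleRate
  chans <- imuChannels()
  n <- seq.int(n0, n1 - 1L)
  t <- n / fs
  cid <- findInterval(t, plan$strikes)
  phi <- (t - plan$strikes[cid]) / plan$durs[cid]

  out <- matrix(0, length(n), 9L, dimnames = list(NULL, chans))
  for (ch in seq_along(chans)) {
    tpl <- cfg@templates[[chans[ch]]]
    wav <- numeric(length(n))
    for (k in seq_along(tpl$amp)) {
      wav <- wav + tpl$amp[k] * cos(2 * pi * k * phi + tpl$phase[k])
    }
    out[, ch] <- tpl$offset * plan$offMul[cid, ch] +
      plan$cycAmp[cid, ch] * wav
  }

  if (any(cfg@noiseSd > 0)) {
    Nfull <- round(cfg@duration * fs)
    sds <- cfg@noiseSd[chans]
    # plain set.seed() in the loop for speed; caller-visible RNG state is
    # saved and restored once around the whole block
    rngState <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(rngState)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", rngState, envir = globalenv())
      }
    }, add = TRUE)
    runs <- rle(cid)
    rowEnd <- cumsum(runs$lengths)
    rowStart <- rowEnd - runs$lengths + 1L
    for (jj in seq_along(runs$values)) {
      i <- runs$values[jj]
      # noise block length of the cycle in the *full* bout, so windowed and
      # full synthesis draw identical values
      len <- if (i < plan$nCyc) plan$firstSample[i + 1L] - plan$firstSample[i]
             else Nfull - plan$firstSample[i]
      rows <- rowStart[jj]:rowEnd[jj]
      local <- n[rows] - plan$firstSample[i] + 1L
      set.seed(plan$noiseSeeds[i])
      noise <- matrix(rnorm(len * 9L), len, 9L)
      out[rows, ] <- out[rows, ] + noise[local, , drop = FALSE] *
        rep(sds, each = length(rows))
    }
  }

  # device full-scale clipping and angle range conventions
  out[, 1:3] <- pmin(pmax(out[, 1:3], -.ACC_FS), .ACC_FS)
  out[, 4:6] <- pmin(pmax(out[, 4:6], -.GYR_FS), .GYR_FS)
  out[, "gx"] <- wrapAngle180(out[, "gx"])
  out[, "gz"] <- wrapAngle180(out[, "gz"])
  out[, "gy"] <- foldAngle90(out[, "gy"])
  out
}

.strikeMeta <- function(cfg, plan) {
  # ground truth excludes the pre-bout strike (its head segment is an
  # incomplete cycle); the terminal strike past the bout end is kept since
  # it closes the last complete cycle
  inBout <- plan$strikes >= 0
  list(strikes = plan$strikes[inBout], strikeIdx0 = plan$firstSample[inBout],
       seed = cfg@seed, cadence = cfg@cadence)
}

#' Simulate one brisk-walking bout
#'
#' Generates a full heel-IMU recording of `duration` at `sampleRate`
#' according to the simulator configuration. The true heel-strike times are
#' stored in the recording's metadata (`meta$strikes`, seconds; the list
#' includes the terminal strike that closes the last complete cycle, so a
#' 1-minute bout at 1 Hz cadence and zero jitter carries 61 strikes
#' delimiting 60 complete cycles).
#'
#' @param config A [GaitSimConfig-class], see [gaitSimConfig()].
#' @param subjectId Subject label stored in the recording.
#' @return An [ImuRecording-class] of `round(duration * sampleRate)`
#'   samples.
#' @examples
#' rec <- simulateBout(gaitSimConfig(durationMin = 1, seed = 3))
#' rec
#' @seealso [simulateWindows()] for the exact windows-only shortcut,
#'   [trueStrikeIndices()] to recover ground-truth strike sample indices.
#' @export
simulateBout <- function(config, subjectId = "sim") {
  stopifnot(is(config, "GaitSimConfig"))
  validObject(config)
  plan <- .simPlan(config)
  N <- round(config@duration * config@sampleRate)
  ImuRecording(.synthRange(config, plan, 0L, N),
               sampleRate = config@sampleRate, t0 = 0,
               subjectId = subjectId, meta = .strikeMeta(config, plan))
}

#' Simulate only the analysis windows of a bout
#'
#' Synthesizes just the samples inside the requested windows of the bout
#' described by `config`. The result is bit-identical to extracting the
#' same windows from [simulateBout()] with the same configuration (strike
#' times and per-cycle random draws are planned for the whole bout; sensor
#' noise uses per-cycle sub-seeds), at a fraction of the cost. Used for
#' cohort-scale simulation studies.
#'
#' @inheritParams simulateBout
#' @param windows Named list of [WindowSpec-class], e.g.
#'   [analysisWindows()].
#' @return Named list of [ImuRecording-class] objects, one per window,
#'   each with `t0` set to the window start on the bout clock.
#' @export
simulateWindows <- function(config, windows = analysisWindows(),
                            subjectId = "sim") {
  stopifnot(is(config, "GaitSimConfig"))
  validObject(config)
  plan <- .simPlan(config)
  N <- round(config@duration * config@sampleRate)
  meta <- .strikeMeta(config, plan)
  out <- lapply(windows, function(w) {
    n0 <- round(w@start * config@sampleRate)
    n1 <- round(w@end * config@sampleRate)
    if (n1 > N) stop("window '", w@label, "' exceeds the bout duration")
    ImuRecording(.synthRange(config, plan, n0, n1),
                 sampleRate = config@sampleRate, t0 = w@start,
                 subjectId = subjectId, meta = meta)
  })
  names(out) <- vapply(windows, function(w) w@label, character(1))
  out
}

#' Ground-truth heel-strike sample indices of a simulated recording
#'
#' Converts the strike times carried in a simulated recording's metadata to
#' 1-based sample indices local to the recording (window or full bout),
#' keeping only strikes whose sample falls inside the recording; these are
#' the strikes a detector operating on the recording could find.
#'
#' @param recording An [ImuRecording-class] produced by [simulateBout()] or
#'   [simulateWindows()].
#' @return Integer vector of 1-based sample indices.
#' @export
trueStrikeIndices <- function(recording) {
  idx0 <- recording@meta$strikeIdx0
  if (is.null(idx0)) stop("recording carries no ground-truth strikes")
  off <- as.integer(round(recording@t0 * recording@sampleRate))
  local <- as.integer(idx0) - off + 1L
  local[local >= 1L & local <= nSamples(recording)]
}

#' Simulate a cohort of walking bouts
#'
#' Generates `n` subjects' bouts from a shared configuration, giving each
#' subject an independent seed derived from `seed`. By default only the
#' analysis windows are synthesized (see [simulateWindows()]).
#'
#' @param config A [GaitSimConfig-class] shared by all subjects.
#' @param n Number of subjects (default 18, a typical elderly cohort size
#'   for treadmill fatigue protocols).
#' @param seed Master seed for the cohort; per-subject seeds are drawn from
#'   it. Defaults to the config seed.
#' @param windows Windows to synthesize, or `NULL` for full bouts.
#' @return List of length `n`; each element is a named list of window
#'   recordings (or a single [ImuRecording-class] if `windows = NULL`).
#'   Subject labels are `"S01"`, `"S02"`, ...
#' @export
simulateCohort <- function(config, n = 18L, seed = config@seed,
                           windows = analysisWindows()) {
  stopifnot(n >= 1L)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg@seed <- seeds[i]
    id <- sprintf("S%02d", i)
    if (is.null(windows)) simulateBout(cfg, subjectId = id)
    else simulateWindows(cfg, windows = windows, subjectId = id)
  })
}
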