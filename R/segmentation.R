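# Heel-strike detection and gait-cycle delimitation.
#
# With the sensor on the posterior heel, the medial-lateral angular
# velocity (wx) shows a sharp peak at each heel strike, the standard IMU
# gait landmark. Strikes are local maxima of wx above an adaptive
# threshold; consecutive strikes delimit one gait cycle of the instrumented
# foot. Partial segments at the window edges are dropped ("incomplete gait
# cycles are ignored"), as are candidate cycles outside the physiological
# duration gates.

# strictly interior local maxima of x above `height`, at least `minDist`
# samples apart; boundary samples never qualify, so partial peak shapes cut
# by the window edges cannot spawn spurious strikes
.findPeaks <- function(x, height, minDist) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  mid <- x[2:(n - 1)]
  cand <- 1L + which(mid >= x[1:(n - 2)] & mid > x[3:n])
  cand <- cand[x[cand] >= height]
  if (length(cand) <= 1L) return(cand)
  # greedily keep the tallest peaks subject to the separation constraint
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  acc <- integer(0)
  for (p in ord) {
    if (!length(acc) || min(abs(acc - p)) >= minDist) acc <- c(acc, p)
  }
  sort(acc)
}

#' Detect heel strikes in a windowed recording
#'
#' Heel strikes are local maxima of the medial-lateral angular-velocity
#' channel (`wx`) exceeding an adaptive threshold (half the 90th percentile
#' of `|wx|` in the window, robust to amplitude drift across the bout),
#' separated by at least `minCycle` seconds.
#'
#' @param window An [ImuRecording-class] (typically one analysis window).
#' @param minCycle Minimum cycle duration in seconds (default 0.6).
#' @return Integer vector of 1-based strike sample indices (possibly
#'   empty).
#' @seealso [segmentCycles()]
#' @export
detectStrikes <- function(window, minCycle = 0.6) {
  stopifnot(is(window, "ImuRecording"))
  wx <- imuData(window)[, "wx"]
  thr <- 0.5 * quantile(abs(wx), 0.9, names = FALSE)
  if (!is.finite(thr) || thr <= 0) return(integer(0))
  .findPeaks(wx, height = thr,
             minDist = round(minCycle * window@sampleRate))
}

#' Delimit complete gait cycles in a windowed recording
#'
#' Consecutive detected heel strikes delimit candidate cycles
#' `[strike_k, strike_k+1)` (1-based half-open sample intervals). The
#' partial segments before the first and after the last strike are
#' dropped, and candidate cycles with durations outside
#' `[minCycle, maxCycle]` are discarded. The default gates 0.6-2.5 s
#' bracket elderly brisk-walking cycle times (~1 s at ~3.9 km/h).
#'
#' A window with fewer than two detected strikes yields zero cycles; this
#' is a data-quality condition for the caller, not an error.
#'
#' @inheritParams detectStrikes
#' @param maxCycle Maximum cycle duration in seconds (default 2.5).
#' @return A data.frame with integer columns `start` (inclusive) and `end`
#'   (exclusive); cycle `i` spans samples `start[i]:(end[i]-1)`.
#' @examples
#' w <- simulateWindows(gaitSimConfig(durationMin = 1, seed = 2),
#'                      windows = list(windowSpec("baseline", 0, 60)))[[1]]
#' cyc <- segmentCycles(w)
#' nrow(cyc)
#' @export
segmentCycles <- function(window, minCycle = 0.6, maxCycle = 2.5) {
  strikes <- detectStrikes(window, minCycle = minCycle)
  if (length(strikes) < 2L)
    return(data.frame(start = integer(0), end = integer(0)))
  cyc <- data.frame(start = strikes[-length(strikes)], end = strikes[-1L])
  durs <- (cyc$end - cyc$start) / window@sampleRate
  cyc[durs >= minCycle & durs <= maxCycle, , drop = FALSE]
}

#' Score detected strikes against ground truth
#'
#' Matches detected strike indices to ground-truth indices one-to-one
#' within a tolerance and reports recall (true strikes found) and
#' precision (detections that are true).
#'
#' @param detected,truth Integer vectors of 1-based strike sample indices.
#' @param tol Matching tolerance in samples (default 3, i.e. 60 ms at
#'   50 Hz).
#' @return List with `recall`, `precision`, `nMatched`.
#' @export
strikeScore <- function(detected, truth, tol = 3L) {
  matched <- 0L
  avail <- truth
  for (d in detected) {
    if (!length(avail)) break
    j <- which.min(abs(avail - d))
    if (abs(avail[j] - d) <= tol) {
      matched <- matched + 1L
      avail <- avail[-j]
    }
  }
  list(recall = if (length(truth)) matched / length(truth) else NA_real_,
       precision = if (length(detected)) matched / length(detected)
                   else NA_real_,
       nMatched = matched)
}
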