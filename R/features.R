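# The ten per-cycle signal statistics and baseline-ratio normalization.
#
# Conventions (population, no small-sample bias corrections): variance is
# the mean squared deviation; skewness the Fisher-Pearson m3/m2^(3/2);
# kurtosis the excess m4/m2^2 - 3 (normal -> 0). Signal power ("energy
# consumption", EC) is the mean of squared samples over the cycle - the
# finite-support evaluation of the limiting power integral - so EC = RMS^2
# holds exactly per cycle. MAD is the raw median absolute deviation
# (median(|x - median(x)|), no normal-consistency constant). "Amplitude
# range" is max(x) - min(x) of the signed signal; the maximum and minimum
# of |x| are separate statistics.

#' Compute one signal statistic of a sample sequence
#'
#' The per-cycle statistics used throughout the pipeline: `"mad"` (median
#' absolute deviation, unscaled), `"kurtosis"` (population excess),
#' `"skewness"` (population Fisher-Pearson), `"rms"`, `"variance"`
#' (population), `"max_abs"`, `"min_abs"`, `"range"` (max - min of the
#' signed signal), `"median_abs"` (median of `|x|`) and `"ec"` (signal
#' power, the mean of squared samples).
#'
#' Zero-variance input makes skewness and kurtosis 0/0; they are defined as
#' 0 in that case. Kurtosis, skewness and variance require at least two
#' samples.
#'
#' @param x Non-empty numeric vector (one gait cycle's samples of one
#'   channel).
#' @param feature One of [gaitFeatures()].
#' @return A scalar.
#' @examples
#' featureValue(c(0, 3, 4), "ec")    # 25/3
#' featureValue(c(0, 3, 4), "rms")   # sqrt(25/3)
#' featureValue(1:5, "mad")          # 1
#' @export
featureValue <- function(x, feature = gaitFeatures()) {
  feature <- match.arg(feature)
  if (length(x) == 0L) stop("empty input sequence")
  if (feature %in% c("kurtosis", "skewness", "variance") && length(x) < 2L)
    stop("'", feature, "' needs at least two samples")
  switch(feature,
    mad        = median(abs(x - median(x))),
    kurtosis   = {
      m2 <- mean((x - mean(x))^2)
      if (m2 <= 0) 0 else mean((x - mean(x))^4) / m2^2 - 3
    },
    skewness   = {
      m2 <- mean((x - mean(x))^2)
      if (m2 <= 0) 0 else mean((x - mean(x))^3) / m2^1.5
    },
    rms        = sqrt(mean(x^2)),
    variance   = mean((x - mean(x))^2),
    max_abs    = max(abs(x)),
    min_abs    = min(abs(x)),
    range      = max(x) - min(x),
    median_abs = median(abs(x)),
    ec         = mean(x^2)
  )
}

# grouped median of already-group-sorted values: starts/ends are group
# bounds in the sorted vector, len the group sizes
.groupedMedianSorted <- function(xs, starts, ends, len) {
  lo <- starts + (len - 1L) %/% 2L
  hi <- starts + len %/% 2L
  (xs[lo] + xs[hi]) / 2
}

# all ten statistics for every cycle of one channel in one pass;
# x: channel samples concatenated over cycles, cid: cycle id per sample
# (1..nCyc, non-decreasing), len: samples per cycle
.groupedFeatures <- function(x, cid, len) {
  nCyc <- length(len)
  ends <- cumsum(len)
  starts <- ends - len + 1L

  # grouped power sums via cumulative sums over the cycle-contiguous layout
  gsum <- function(v) diff(c(0, cumsum(v)[ends]))
  x2 <- x * x
  s1 <- gsum(x)
  s2 <- gsum(x2)
  s3 <- gsum(x2 * x)
  s4 <- gsum(x2 * x2)
  mu <- s1 / len
  ec <- s2 / len
  m2 <- ec - mu^2
  m3 <- s3 / len - 3 * mu * ec + 2 * mu^3
  m4 <- s4 / len - 4 * mu * (s3 / len) + 6 * mu^2 * ec - 3 * mu^4
  m2 <- pmax(m2, 0)
  ok <- m2 > .Machine$double.eps * pmax(ec, 1)
  skew <- ifelse(ok, m3 / m2^1.5, 0)
  kurt <- ifelse(ok, m4 / m2^2 - 3, 0)

  o <- order(cid, x)
  xs <- x[o]
  mn <- xs[starts]
  mx <- xs[ends]
  med <- .groupedMedianSorted(xs, starts, ends, len)

  ax <- abs(x)
  o <- order(cid, ax)
  axs <- ax[o]
  minAbs <- axs[starts]
  maxAbs <- axs[ends]
  medAbs <- .groupedMedianSorted(axs, starts, ends, len)

  dev <- abs(x - med[cid])
  o <- order(cid, dev)
  devs <- dev[o]
  madv <- .groupedMedianSorted(devs, starts, ends, len)

  cbind(mad = madv, kurtosis = kurt, skewness = skew, rms = sqrt(ec),
        variance = m2, max_abs = maxAbs, min_abs = minAbs, range = mx - mn,
        median_abs = medAbs, ec = ec)
}

#' Per-cycle feature matrix of one analysis window
#'
#' Applies every statistic in [gaitFeatures()] to each gait cycle's samples
#' of each channel. Equivalent to calling [featureValue()] on each
#' `(cycle, channel)` slice, computed with grouped one-pass kernels.
#'
#' @param window An [ImuRecording-class].
#' @param cycles Cycle table from [segmentCycles()] (columns `start`,
#'   `end`, 1-based half-open). An empty table yields a zero-cycle
#'   [CycleFeatures-class].
#' @param label Window label stored in the result; defaults to
#'   `"baseline"`.
#' @return A [CycleFeatures-class] (9 channels x 10 features x cycles).
#' @export
perCycleFeatures <- function(window, cycles, label = "baseline") {
  stopifnot(is(window, "ImuRecording"), is.data.frame(cycles))
  chans <- imuChannels()
  feats <- gaitFeatures()
  nCyc <- nrow(cycles)
  vals <- array(NA_real_, dim = c(9L, 10L, nCyc),
                dimnames = list(chans, feats, NULL))
  if (nCyc > 0L) {
    if (any(cycles$start < 1L) || any(cycles$end > nSamples(window) + 1L) ||
        any(cycles$end <= cycles$start))
      stop("cycle bounds outside the window")
    len <- cycles$end - cycles$start
    idx <- sequence(len, from = cycles$start)
    cid <- rep.int(seq_len(nCyc), len)
    d <- imuData(window)
    for (ch in seq_along(chans)) {
      f <- .groupedFeatures(d[idx, ch], cid, len)
      vals[ch, , ] <- t(f[, feats, drop = FALSE])
    }
  }
  new("CycleFeatures", windowLabel = label, values = vals)
}

#' Window-average of per-cycle features
#'
#' Arithmetic mean over cycles of each (channel, feature) statistic: the
#' per-window aggregate that is subsequently normalized to baseline.
#'
#' @param features A [CycleFeatures-class] with at least one cycle.
#' @return Numeric 9 x 10 matrix (channels x features).
#' @export
windowMean <- function(features) {
  stopifnot(is(features, "CycleFeatures"))
  if (nCycles(features) == 0L)
    stop("no complete gait cycles in window '", features@windowLabel,
         "'; subject-window must be excluded")
  rowMeans(features@values, dims = 2L)
}

#' Normalize window aggregates to the subject's baseline
#'
#' Divides each window's (channel, feature) average by the subject's
#' baseline-window average, making every outcome a unitless ratio with
#' baseline identically 1 and removing between-subject level differences.
#' Entries whose baseline aggregate is exactly zero are flagged `NA`
#' (with a note) rather than emitted as infinities.
#'
#' @param means Named list of three 9 x 10 matrices (from [windowMean()])
#'   with names `baseline`, `min30`, `min60`.
#' @param subject Subject label.
#' @return Long-format data.frame with columns `subject`, `window`,
#'   `channel`, `feature`, `value`, 270 rows.
#' @examples
#' b <- matrix(2, 9, 10, dimnames = list(imuChannels(), gaitFeatures()))
#' tbl <- normalizeToBaseline(list(baseline = b, min30 = b * 1.5,
#'                                 min60 = b * 2), subject = "S01")
#' subset(tbl, channel == "gz" & feature == "rms")$value  # 1, 1.5, 2
#' @export
normalizeToBaseline <- function(means, subject = "S01") {
  stopifnot(identical(sort(names(means)), sort(.WINDOW_LABELS)))
  base <- means$baseline
  zero <- base == 0
  if (any(zero))
    message(sum(zero), " (channel, feature) baseline aggregate(s) are zero",
            " for subject ", subject, "; ratios flagged NA")
  out <- do.call(rbind, lapply(.WINDOW_LABELS, function(w) {
    r <- means[[w]] / base
    if (w == "baseline") r[!zero] <- 1  # exact by definition
    r[zero] <- NA_real_
    data.frame(subject = subject, window = w,
               channel = rep(imuChannels(), times = 10L),
               feature = rep(gaitFeatures(), each = 9L),
               value = as.vector(r))
  }))
  rownames(out) <- NULL
  out
}
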