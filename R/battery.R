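# Cohort assembly and the omnibus + post hoc battery over the 90 blocks.

.CONTRASTS <- list(
  "baseline-min30" = c(1L, 2L),
  "baseline-min60" = c(1L, 3L),
  "min30-min60"    = c(2L, 3L)
)

#' Assemble a cohort table from per-subject normalized feature tables
#'
#' Stacks long-format normalized tables (from [normalizeToBaseline()]) into
#' the `subjects x 3 windows x 90 blocks` array consumed by
#' [runBattery()]. Block names are `"<channel>.<feature>"`.
#'
#' @param tables List of data.frames, one per subject.
#' @return A [CohortTable-class].
#' @export
buildCohortTable <- function(tables) {
  stopifnot(length(tables) >= 1L)
  chans <- imuChannels()
  feats <- gaitFeatures()
  blocks <- as.vector(outer(chans, feats, paste, sep = "."))
  subjects <- vapply(tables, function(t) as.character(t$subject[1]),
                     character(1))
  arr <- array(NA_real_,
               dim = c(length(tables), 3L, 90L),
               dimnames = list(subjects, .WINDOW_LABELS, blocks))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    key <- paste(t$channel, t$feature, sep = ".")
    for (w in .WINDOW_LABELS) {
      sel <- t$window == w
      arr[i, w, key[sel]] <- t$value[sel]
    }
  }
  log <- character(0)
  nNA <- sum(is.na(arr))
  if (nNA > 0L)
    log <- sprintf("%d NA cells (flagged windows); listwise exclusion per block",
                   nNA)
  new("CohortTable", data = arr, log = log)
}

#' Run the repeated-measures nonparametric battery over a cohort
#'
#' For each of the 90 (channel, feature) blocks: a Friedman omnibus across
#' the baseline/min30/min60 columns ([friedmanTest()]); for blocks with
#' omnibus `p < alpha`, the three pairwise Wilcoxon signed-rank contrasts
#' ([wilcoxonSignedRank()]) with Bonferroni-adjusted p-values
#' ([bonferroniAdjust()], family size 3). Pairwise contrasts are starred
#' when the adjusted p falls below `alpha` (equivalently raw
#' `p < alpha/3` ~ 0.017). Subjects with NA cells in a block are excluded
#' listwise for that block (logged); a block with fewer than 2 surviving
#' subjects is omitted with a log entry.
#'
#' No correction is applied across the 90 omnibus tests themselves (a
#' deliberate mirror of the three-window design; see the vignette for the
#' multiplicity caveat).
#'
#' @param cohort A [CohortTable-class].
#' @param alpha Family significance level for the omnibus (default 0.05).
#' @param posthocM Number of comparisons in the post hoc family
#'   (default 3).
#' @return A [StatReport-class].
#' @export
runBattery <- function(cohort, alpha = 0.05, posthocM = 3L) {
  stopifnot(is(cohort, "CohortTable"), alpha > 0, alpha < 1)
  arr <- cohort@data
  blocks <- dimnames(arr)[[3]]
  log <- cohort@log
  fr <- vector("list", length(blocks))
  ph <- vector("list", length(blocks))
  for (j in seq_along(blocks)) {
    blk <- arr[, , j, drop = FALSE]
    dim(blk) <- dim(arr)[1:2]
    keep <- rowSums(is.na(blk)) == 0L
    if (sum(keep) < nrow(blk))
      log <- c(log, sprintf("block %s: %d subject(s) excluded listwise",
                            blocks[j], sum(!keep)))
    if (sum(keep) < 2L) {
      log <- c(log, sprintf("block %s omitted: fewer than 2 subjects",
                            blocks[j]))
      next
    }
    blk <- blk[keep, , drop = FALSE]
    chFeat <- strsplit(blocks[j], ".", fixed = TRUE)[[1]]
    ft <- friedmanTest(blk)
    sig <- ft$p.value < alpha
    fr[[j]] <- data.frame(channel = chFeat[1], feature = chFeat[2],
                          n = nrow(blk), statistic = ft$statistic,
                          p.value = ft$p.value, significant = sig)
    if (sig) {
      ph[[j]] <- do.call(rbind, lapply(names(.CONTRASTS), function(cn) {
        cols <- .CONTRASTS[[cn]]
        wt <- wilcoxonSignedRank(blk[, cols[1]], blk[, cols[2]])
        adj <- bonferroniAdjust(wt$p.value, posthocM)
        if (wt$degenerate)
          log <<- c(log, sprintf("block %s contrast %s: all differences zero",
                                 blocks[j], cn))
        data.frame(channel = chFeat[1], feature = chFeat[2], contrast = cn,
                   p.value = wt$p.value, p.adjusted = adj,
                   significant = adj < alpha,
                   n.zero.dropped = wt$n.zero.dropped,
                   degenerate = wt$degenerate)
      }))
    }
  }
  friedman <- do.call(rbind, fr[!vapply(fr, is.null, logical(1))])
  posthoc <- do.call(rbind, ph[!vapply(ph, is.null, logical(1))])
  if (is.null(posthoc))
    posthoc <- data.frame(channel = character(0), feature = character(0),
                          contrast = character(0), p.value = numeric(0),
                          p.adjusted = numeric(0), significant = logical(0),
                          n.zero.dropped = integer(0),
                          degenerate = logical(0))
  rownames(friedman) <- rownames(posthoc) <- NULL
  new("StatReport", friedman = friedman, posthoc = posthoc,
      alpha = alpha, posthocAlpha = alpha / posthocM,
      nSubjects = nSubjects(cohort), log = log)
}

#' Report tables
#'
#' `friedmanWideTable()` casts the omnibus results into the features x
#' channels grid of Friedman p-values (starred at `p < alpha`);
#' `posthocTable()` lists, for each significant block, the three window
#' contrasts with raw and Bonferroni-adjusted p-values (starred at
#' adjusted `p < alpha`).
#'
#' @param report A [StatReport-class].
#' @param digits Rounding for display (default 3).
#' @return A data.frame.
#' @export
friedmanWideTable <- function(report, digits = 3) {
  stopifnot(is(report, "StatReport"))
  fr <- report@friedman
  out <- data.frame(feature = gaitFeatures())
  for (ch in imuChannels()) {
    col <- vapply(gaitFeatures(), function(ft) {
      row <- fr[fr$channel == ch & fr$feature == ft, ]
      if (!nrow(row)) return(NA_character_)
      paste0(format(round(row$p.value, digits), nsmall = digits),
             if (row$significant) " *" else "")
    }, character(1))
    out[[ch]] <- unname(col)
  }
  out
}

#' @rdname friedmanWideTable
#' @export
posthocTable <- function(report, digits = 3) {
  stopifnot(is(report, "StatReport"))
  ph <- report@posthoc
  if (!nrow(ph)) return(data.frame())
  fmt <- function(p) format(round(p, digits), nsmall = digits)
  out <- data.frame(signal = ph$channel, feature = ph$feature,
                    contrast = ph$contrast, p = fmt(ph$p.value),
                    p.adjusted = paste0(fmt(ph$p.adjusted),
                                        ifelse(ph$significant, " *", "")))
  out
}

#' Write the two report tables as delimited text
#'
#' @param report A [StatReport-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
writeStatReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "friedman_by_channel.tsv")
  p2 <- file.path(dir, "posthoc_contrasts.tsv")
  data.table::fwrite(friedmanWideTable(report), p1, sep = "\t")
  data.table::fwrite(posthocTable(report), p2, sep = "\t")
  invisible(c(p1, p2))
}

#' Reference p-value grids from the motivating published study
#'
#' Transcriptions of the published summary tables of a 60-minute elderly
#' brisk-walking fatigue study (18 subjects, heel IMU, the same 10-feature
#' x 9-channel design): `referenceFriedmanP()` returns the features x
#' channels grid of Friedman p-values as printed;
#' `referencePosthocP()` the post hoc contrasts (raw and adjusted p) of
#' the blocks that reached omnibus significance. These printed values are
#' inputs for consistency checks (Bonferroni arithmetic, significant-block
#' counting); the underlying raw recordings were never deposited.
#'
#' @return A data.frame.
#' @export
referenceFriedmanP <- function() {
  path <- system.file("extdata", "reference_friedman_p.tsv",
                      package = "heelgait", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' @rdname referenceFriedmanP
#' @export
referencePosthocP <- function() {
  path <- system.file("extdata", "reference_posthoc_p.tsv",
                      package = "heelgait", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}
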