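# The repeated-measures nonparametric test battery.

#' Shapiro-Wilk normality screen
#'
#' Used to justify the nonparametric path; the result is recorded, never
#' used to gate any computation.
#'
#' @param values Numeric vector, 3 <= n <= 5000, not constant.
#' @return List with `statistic` (W) and `p.value`.
#' @export
normalityScreen <- function(values) {
  n <- length(values)
  if (n < 3L) stop("normality screen needs at least 3 values")
  if (n > 5000L) stop("normality screen supports at most 5000 values")
  if (length(unique(values)) == 1L)
    stop("normality screen is degenerate for a constant sequence")
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p.value = sw$p.value)
}

#' Friedman omnibus test of a subjects x conditions block
#'
#' Rank-based repeated-measures omnibus across the (three) time windows:
#' within-subject average ranks, tie-corrected chi-squared statistic, p
#' from the chi-squared distribution with k-1 degrees of freedom (the
#' standard approximation at cohort sizes around 18). For very small
#' cohorts an exact permutation p over all `factorial(k)^n` within-row
#' orderings is available.
#'
#' A block whose rows are all fully tied (no rank variation anywhere) has
#' statistic 0 and p 1.
#'
#' @param block Numeric matrix, subjects x k conditions (k = 3 for the
#'   baseline/min30/min60 design), no missing values.
#' @param exact Use the exact permutation distribution (requires
#'   `nrow(block) <= 8` and `ncol(block) <= 3`). Default FALSE.
#' @return List with `statistic`, `p.value`, `df`.
#' @examples
#' b <- matrix(c(1, 1, 1, 1, 1, 1.1, 1.2, 1.1, 1.3, 1.2, 1.3, 1.4), 4)
#' friedmanTest(b)
#' @export
friedmanTest <- function(block, exact = FALSE) {
  block <- as.matrix(block)
  if (anyNA(block)) stop("block contains missing values; exclude upstream")
  n <- nrow(block)
  k <- ncol(block)
  if (n < 2L) stop("Friedman test needs at least 2 subjects")
  stat <- .friedmanStat(block)
  p <- pchisq(stat, df = k - 1L, lower.tail = FALSE)
  if (stat == 0) p <- 1
  if (exact) {
    if (n > 8L || k > 3L)
      stop("exact permutation supported for n <= 8 subjects, k <= 3")
    p <- .friedmanExactP(block)
  }
  list(statistic = stat, p.value = p, df = k - 1L)
}

# tie-corrected Friedman chi-squared statistic,
# 12 * sum_j (R_j - n(k+1)/2)^2 / (nk(k+1) - sum(t^3 - t)/(k - 1));
# a fully tied block (zero denominator) has statistic 0
.friedmanStat <- function(block) {
  if (ncol(block) == 3L) return(.friedmanStatK3(block))
  n <- nrow(block)
  k <- ncol(block)
  r <- t(apply(block, 1L, rank))
  ties <- tapply(r, row(r), table)
  denom <- n * k * (k + 1) -
    sum(unlist(lapply(ties, function(u) u^3 - u))) / (k - 1)
  if (denom == 0) return(0)
  (12 * sum((colSums(r) - n * (k + 1) / 2)^2)) / denom
}

# vectorized k = 3 case (the baseline/min30/min60 design): within-row
# average ranks and the tie term from direct pairwise comparisons
.friedmanStatK3 <- function(block) {
  n <- nrow(block)
  x1 <- block[, 1]
  x2 <- block[, 2]
  x3 <- block[, 3]
  e12 <- x1 == x2
  e13 <- x1 == x3
  e23 <- x2 == x3
  r1 <- 1 + (x1 > x2) + (x1 > x3) + 0.5 * (e12 + e13)
  r2 <- 1 + (x2 > x1) + (x2 > x3) + 0.5 * (e12 + e23)
  r3 <- 1 + (x3 > x1) + (x3 > x2) + 0.5 * (e13 + e23)
  allEq <- e12 & e23
  anyTie <- e12 | e13 | e23
  tieSum <- 24 * sum(allEq) + 6 * sum(anyTie & !allEq)
  denom <- 12 * n - tieSum / 2
  if (denom == 0) return(0)
  12 * ((sum(r1) - 2 * n)^2 + (sum(r2) - 2 * n)^2 +
          (sum(r3) - 2 * n)^2) / denom
}

# exact permutation p: enumerate all k!^n equally likely within-row
# permutations of the observed rows
.friedmanExactP <- function(block) {
  n <- nrow(block)
  k <- ncol(block)
  perms <- .allPermutations(k)
  obs <- .friedmanStat(block)
  idx <- rep.int(1L, n)
  nPerm <- nrow(perms)
  total <- nPerm^n
  geq <- 0L
  repeat {
    b <- block
    for (i in seq_len(n)) b[i, ] <- block[i, perms[idx[i], ]]
    if (.friedmanStat(b) >= obs - 1e-12) geq <- geq + 1L
    j <- 1L
    while (j <= n && idx[j] == nPerm) {
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > n) break
    idx[j] <- idx[j] + 1L
  }
  geq / total
}

.allPermutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L))
  sub <- .allPermutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(pos, sub + (sub >= pos))
  }))
}

#' Wilcoxon signed-rank test for paired windows
#'
#' Two-sided paired test. Zero differences are discarded before ranking
#' (Wilcoxon's original rule; the count is reported), ties receive average
#' ranks. For n <= `exactMax` surviving pairs the p-value is exact,
#' computed from the full null distribution of the positive-rank sum over
#' all `2^n` sign assignments (handled by convolution, identical to direct
#' enumeration and valid under ties); otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' If every difference is zero the test is undefined; `p.value` is 1 and
#' `degenerate` is TRUE.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param exactMax Largest n for the exact null distribution (default 25).
#' @return List with `statistic` (positive-rank sum W+), `p.value`,
#'   `n.used`, `n.zero.dropped`, `exact`, `degenerate`.
#' @examples
#' wilcoxonSignedRank(2:7, rep(1, 6))$p.value  # 2/2^6 = 0.03125
#' @export
wilcoxonSignedRank <- function(a, b, exactMax = 25L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  if (anyNA(d)) stop("missing values in paired samples")
  nZero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p.value = 1, n.used = 0L,
                n.zero.dropped = nZero, exact = TRUE, degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    # distribution of W+ over all 2^n sign patterns; double the ranks so
    # average ranks become integers
    r2 <- as.integer(round(2 * r))
    f <- c(1, numeric(sum(r2)))
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(length(f) - ri)])
      f <- f + shifted
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * W))
    pLo <- sum(f[seq_len(w2 + 1L)])
    pHi <- sum(f[(w2 + 1L):length(f)])
    p <- min(1, 2 * min(pLo, pHi))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tieTab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tieTab^3 - tieTab) / 48
    z <- (abs(W - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-z))
    exact <- FALSE
  }
  list(statistic = W, p.value = p, n.used = n, n.zero.dropped = nZero,
       exact = exact, degenerate = FALSE)
}

#' Bonferroni adjustment for a fixed family of comparisons
#'
#' `min(1, m * p)` for each raw p-value, the multiplicative form matching
#' adjusted-p reporting; the equivalent fixed threshold is `alpha / m`
#' (0.05 / 3 ~ 0.017 for the three pairwise window contrasts).
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Number of comparisons in the family (default 3).
#' @return Adjusted p-values, same length as `p`.
#' @examples
#' bonferroniAdjust(c(0.006, 0.17, 0.5))  # 0.018, 0.51, 1
#' @export
bonferroniAdjust <- function(p, m = 3L) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("raw p-values must lie in [0, 1]")
  if (m < 1L) stop("m must be >= 1")
  pmin(1, m * p)
}
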