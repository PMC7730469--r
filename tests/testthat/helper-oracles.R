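# Independent brute-force oracles and small fixture builders.

# sorted-vector median, written independently of stats::median
bruteMedian <- function(v) {
  s <- sort(v)
  m <- length(s)
  if (m %% 2 == 1) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
}

# direct-definition evaluation of each statistic via explicit sums
bruteFeature <- function(x, feature) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  switch(feature,
    mad        = bruteMedian(abs(x - bruteMedian(x))),
    kurtosis   = if (m2 == 0) 0 else (sum((x - mu)^4) / n) / m2^2 - 3,
    skewness   = if (m2 == 0) 0 else (sum((x - mu)^3) / n) / m2^(3 / 2),
    rms        = sqrt(sum(x * x) / n),
    variance   = m2,
    max_abs    = max(abs(x)),
    min_abs    = min(abs(x)),
    range      = max(x) - min(x),
    median_abs = bruteMedian(abs(x)),
    ec         = sum(x * x) / n
  )
}

# from-scratch tie-corrected Friedman chi-squared via the Conover form
# (k-1) * sum_j (R_j - n(k+1)/2)^2 / (A - C), an algebraically different
# route from the package's formula
bruteFriedman <- function(block) {
  n <- nrow(block)
  k <- ncol(block)
  r <- t(apply(block, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  if (A == C) return(list(statistic = 0, p.value = 1))
  stat <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
  list(statistic = stat,
       p.value = pchisq(stat, df = k - 1, lower.tail = FALSE))
}

# exact two-sided Wilcoxon signed-rank p by explicit enumeration of all
# 2^n sign assignments (n <= 16)
bruteWilcoxonP <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  stopifnot(n <= 16)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  total <- 2^n
  Wall <- numeric(total)
  for (m in 0:(total - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    Wall[m + 1] <- sum(r[signs == 1L])
  }
  pLo <- mean(Wall <= W + 1e-9)
  pHi <- mean(Wall >= W - 1e-9)
  min(1, 2 * min(pLo, pHi))
}

# exact size of the nominal-alpha Friedman test at k = 3: null distribution
# of the statistic by convolution over per-subject rank permutations
exactFriedmanSize <- function(n, alpha = 0.05) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  sz <- 3 * n + 1
  dp <- matrix(0, sz, sz)
  dp[1, 1] <- 1
  for (i in seq_len(n)) {
    nxt <- matrix(0, sz, sz)
    for (p in 1:6) {
      r1 <- perms[p, 1]
      r2 <- perms[p, 2]
      nxt[(1 + r1):sz, (1 + r2):sz] <- nxt[(1 + r1):sz, (1 + r2):sz] +
        dp[1:(sz - r1), 1:(sz - r2)] / 6
    }
    dp <- nxt
  }
  idx <- which(dp > 0, arr.ind = TRUE)
  R1 <- idx[, 1] - 1
  R2 <- idx[, 2] - 1
  R3 <- 6 * n - R1 - R2
  stat <- 12 * ((R1 - 2 * n)^2 + (R2 - 2 * n)^2 + (R3 - 2 * n)^2) / (12 * n)
  sum(dp[idx][pchisq(stat, 2, lower.tail = FALSE) < alpha])
}

# noise-free, jitter-free simulator config for exactness tests; short bout
# with analysis windows at minutes 1, 3 and 5
cleanSimConfig <- function(durationMin = 5, seed = 1L, effects = list(),
                           cadence = 1.0) {
  gaitSimConfig(durationMin = durationMin, cadence = cadence,
                cadenceJitterCv = 0, ampCv = 0,
                noiseSd = setNames(rep(0, 9), imuChannels()),
                effects = effects, effectTimesMin = c(3, 5), seed = seed)
}

shortWindows <- function() analysisWindows(c(1, 3, 5))
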