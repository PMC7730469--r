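test_that("Friedman handles degenerate and textbook blocks", {
  same <- matrix(rep(c(1, 1.2, 0.9), each = 5), 5)
  same[] <- 1  # identical everywhere: no rank variation at all
  res <- friedmanTest(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  inc <- matrix(rep(1:3, each = 5), 5)  # every subject strictly increasing
  res <- friedmanTest(inc)
  expect_equal(res$statistic, 10)
  expect_equal(res$p.value, pchisq(10, 2, lower.tail = FALSE))
  expect_equal(res$p.value, 0.0067379, tolerance = 1e-5)

  expect_error(friedmanTest(matrix(1:3, 1)), "2 subjects")
  expect_error(friedmanTest(matrix(c(1, NA, 3, 1, 2, 3), 2, byrow = TRUE)),
               "missing")
})

test_that("Friedman matches an independent rank-based oracle on random blocks", {
  for (seed in 1:60) {
    n <- withr::with_seed(seed, sample(2:20, 1))
    blk <- withr::with_seed(seed + 500, {
      m <- matrix(rnorm(n * 3), n)
      if (seed %% 3 == 0) m[] <- round(m, 0)  # force heavy ties
      m
    })
    mine <- friedmanTest(blk)
    oracle <- bruteFriedman(blk)
    expect_equal(mine$statistic, oracle$statistic, tolerance = 1e-12)
    expect_equal(mine$p.value, oracle$p.value, tolerance = 1e-12)
    ref <- suppressWarnings(stats::friedman.test(blk))
    if (!is.nan(ref$statistic))
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  # k = 4 path against stats::friedman.test
  blk4 <- withr::with_seed(11, matrix(rnorm(32), 8, 4))
  expect_equal(friedmanTest(blk4)$statistic,
               unname(suppressWarnings(stats::friedman.test(blk4))$statistic),
               tolerance = 1e-12)
})

test_that("Friedman is invariant under monotone per-value transforms", {
  for (seed in 1:10) {
    blk <- withr::with_seed(seed, matrix(rnorm(30), 10))
    a <- friedmanTest(blk)
    b <- friedmanTest(blk^3)  # strictly monotone over the reals
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p.value, b$p.value)
  }
})

test_that("exact Friedman permutation p is correct for tiny cohorts", {
  # both rows strictly increasing: only aligned permutation pairs reach the
  # maximal statistic, so p = 6/36
  blk <- rbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(friedmanTest(blk, exact = TRUE)$p.value, 1 / 6)
  expect_error(friedmanTest(matrix(rnorm(30), 10), exact = TRUE), "n <= 8")
})

test_that("Wilcoxon signed-rank reproduces exact enumeration", {
  expect_equal(wilcoxonSignedRank(2:7, rep(1, 6))$p.value, 2 / 2^6)
  res <- wilcoxonSignedRank(rep(1, 6), rep(1, 6))
  expect_true(res$degenerate)
  expect_equal(res$p.value, 1)
  expect_identical(res$n.zero.dropped, 6L)

  for (seed in 1:40) {
    n <- withr::with_seed(seed, sample(5:12, 1))
    a <- withr::with_seed(seed + 900, rnorm(n))
    b <- withr::with_seed(seed + 901, rnorm(n))
    if (seed %% 3 == 0) {
      a <- round(a, 0)  # ties and zero differences
      b <- round(b, 0)
    }
    expect_equal(wilcoxonSignedRank(a, b)$p.value, bruteWilcoxonP(a, b),
                 tolerance = 1e-12, label = paste("seed", seed))
  }
})

test_that("Wilcoxon agrees with stats::wilcox.test on its exact domain", {
  for (seed in 1:20) {
    n <- withr::with_seed(seed, sample(6:20, 1))
    a <- withr::with_seed(seed + 70, rnorm(n))
    b <- withr::with_seed(seed + 71, rnorm(n))
    expect_equal(wilcoxonSignedRank(a, b)$p.value,
                 stats::wilcox.test(a, b, paired = TRUE,
                                    exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample path with ties: normal approximation with tie correction
  a <- withr::with_seed(5, round(rnorm(40, sd = 3)))
  b <- withr::with_seed(6, round(rnorm(40, sd = 3)))
  mine <- wilcoxonSignedRank(a, b)
  expect_false(mine$exact)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("Bonferroni adjustment multiplies, caps and stays monotone", {
  expect_equal(bonferroniAdjust(0.006), 0.018)
  expect_equal(bonferroniAdjust(0.17), 0.51)
  expect_equal(bonferroniAdjust(0.5), 1)
  expect_equal(bonferroniAdjust(0.02, m = 10), 0.2)
  p <- sort(withr::with_seed(2, runif(50)))
  adj <- bonferroniAdjust(p)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj <= 1))
  expect_error(bonferroniAdjust(1.2), "\\[0, 1\\]")
  expect_error(bonferroniAdjust(-0.1), "\\[0, 1\\]")
})

test_that("normality screen separates normal from skewed samples", {
  pNorm <- vapply(1:100, function(s)
    normalityScreen(withr::with_seed(s, rnorm(50)))$p.value, numeric(1))
  pExp <- vapply(1:100, function(s)
    normalityScreen(withr::with_seed(s + 4000, rexp(50)))$p.value, numeric(1))
  expect_gte(mean(pNorm > 0.05), 0.9)
  expect_gte(mean(pExp < 0.05), 0.9)
  expect_error(normalityScreen(rep(1, 10)), "constant")
  expect_error(normalityScreen(c(1, 2)), "at least 3")
})

test_that("battery gates post hoc tests on omnibus significance", {
  nSub <- 18
  blocks <- as.vector(outer(imuChannels(), gaitFeatures(), paste, sep = "."))
  arr <- array(1, dim = c(nSub, 3, 90),
               dimnames = list(sprintf("S%02d", 1:nSub),
                               c("baseline", "min30", "min60"), blocks))
  noise <- withr::with_seed(42, array(rnorm(nSub * 2 * 90, sd = 0.01),
                                      dim = c(nSub, 2, 90)))
  arr[, 2:3, ] <- 1 + noise
  # strong fatigue-like shift on the gz rms block at both later windows
  bi <- which(blocks == "gz.rms")
  arr[, 2, "gz.rms"] <- 1.25 + noise[, 1, bi]
  arr[, 3, "gz.rms"] <- 1.45 + noise[, 2, bi]
  cohort <- new("CohortTable", data = arr, log = character(0))
  rpt <- runBattery(cohort, alpha = 0.05)

  fr <- rpt@friedman
  gz <- fr[fr$channel == "gz" & fr$feature == "rms", ]
  expect_true(gz$significant)
  ph <- rpt@posthoc
  expect_setequal(unique(paste(ph$channel, ph$feature)),
                  paste(fr$channel, fr$feature)[fr$significant])
  gzph <- ph[ph$channel == "gz" & ph$feature == "rms", ]
  expect_identical(nrow(gzph), 3L)
  expect_true(all(gzph$significant[gzph$contrast != "min30-min60"]))
  expect_equal(gzph$p.adjusted, pmin(1, 3 * gzph$p.value))
  expect_equal(rpt@posthocAlpha, 0.05 / 3)

  # constant baseline column of 1s never breaks the ranking
  expect_true(all(is.finite(fr$statistic)))
})

test_that("battery excludes subjects listwise per block", {
  nSub <- 10
  blocks <- as.vector(outer(imuChannels(), gaitFeatures(), paste, sep = "."))
  arr <- array(rep(1, nSub * 3 * 90), dim = c(nSub, 3, 90),
               dimnames = list(sprintf("S%02d", 1:nSub),
                               c("baseline", "min30", "min60"), blocks))
  arr[, 2:3, ] <- withr::with_seed(1, 1 + rnorm(nSub * 2 * 90, sd = 0.05))
  arr[3, 2, "ax.mad"] <- NA
  rpt <- runBattery(new("CohortTable", data = arr, log = character(0)))
  fr <- rpt@friedman
  expect_identical(fr$n[fr$channel == "ax" & fr$feature == "mad"], 9L)
  expect_identical(fr$n[fr$channel == "ax" & fr$feature == "rms"], 10L)
  expect_true(any(grepl("excluded listwise", rpt@log)))
})

test_that("EC and RMS rank identically for single-cycle windows but can differ for means", {
  # single cycle per window: ec = rms^2 exactly, a monotone map on
  # positives, so Friedman results coincide
  nSub <- 8
  rms <- withr::with_seed(3, matrix(1 + 0.2 * abs(rnorm(nSub * 3)), nSub))
  fRms <- friedmanTest(rms)
  fEc <- friedmanTest(rms^2)
  expect_equal(fRms$statistic, fEc$statistic)
  expect_equal(fRms$p.value, fEc$p.value)

  # multi-cycle window means: mean(ec) is not (mean rms)^2, orderings and
  # hence ranks can genuinely differ
  rmsMeans <- rbind(c(2, 2.2), c(2, 2.2), c(2, 2.2))
  ecMeans <- rbind(c(5, 4.84), c(5, 4.84), c(5, 4.84))
  expect_true(all((rmsMeans[, 1] < rmsMeans[, 2]) !=
                    (ecMeans[, 1] < ecMeans[, 2])))
})
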