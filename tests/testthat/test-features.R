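test_that("feature values match closed-form cases", {
  x <- c(2, 2, 2, 2)
  expect_equal(featureValue(x, "ec"), 4)
  expect_equal(featureValue(x, "rms"), 2)
  expect_equal(featureValue(x, "mad"), 0)
  expect_equal(featureValue(x, "variance"), 0)
  expect_equal(featureValue(x, "range"), 0)
  expect_equal(featureValue(x, "skewness"), 0)  # zero-variance convention
  expect_equal(featureValue(x, "kurtosis"), 0)

  y <- c(0, 3, 4)
  expect_equal(featureValue(y, "ec"), 25 / 3)
  expect_equal(featureValue(y, "rms"), sqrt(25 / 3))
  expect_equal(featureValue(y, "range"), 4)
  expect_equal(featureValue(y, "median_abs"), 3)

  z <- 1:5
  expect_equal(featureValue(z, "mad"), 1)
  expect_equal(featureValue(z, "skewness"), 0)
})

test_that("degenerate feature inputs are rejected", {
  expect_error(featureValue(numeric(0), "rms"), "empty")
  expect_error(featureValue(3, "variance"), "two samples")
  expect_error(featureValue(3, "kurtosis"), "two samples")
  expect_equal(featureValue(3, "rms"), 3)
})

test_that("EC equals squared RMS per cycle but not per window mean", {
  for (seed in 1:20) {
    x <- withr::with_seed(seed, rnorm(40, sd = 3))
    expect_equal(featureValue(x, "ec"), featureValue(x, "rms")^2,
                 tolerance = 1e-14)
  }
  # two cycles with RMS {1, 3}: mean EC = 5 but (mean RMS)^2 = 4
  d <- matrix(0, 100, 9, dimnames = list(NULL, imuChannels()))
  d[1:50, ] <- 1
  d[51:100, ] <- 3
  w <- ImuRecording(d, sampleRate = 50)
  cf <- perCycleFeatures(w, data.frame(start = c(1L, 51L), end = c(51L, 101L)))
  m <- windowMean(cf)
  expect_equal(m["ay", "ec"], 5)
  expect_equal(m["ay", "rms"], 2)
  expect_false(isTRUE(all.equal(m["ay", "ec"], m["ay", "rms"]^2)))
})

test_that("grouped per-cycle kernel agrees with featureValue on slices", {
  w <- simulateWindows(gaitSimConfig(durationMin = 2, seed = 31L),
                       windows = list(windowSpec("baseline", 0, 60)))[[1]]
  cyc <- segmentCycles(w)
  cf <- perCycleFeatures(w, cyc)
  expect_identical(dim(featureValues(cf)), c(9L, 10L, nrow(cyc)))
  d <- imuData(w)
  for (i in c(1L, 7L, nrow(cyc))) {
    slice <- d[cyc$start[i]:(cyc$end[i] - 1L), ]
    for (ch in c("ax", "wx", "gz")) {
      for (f in gaitFeatures()) {
        expect_equal(featureValues(cf)[ch, f, i],
                     featureValue(slice[, ch], f),
                     tolerance = 1e-12,
                     label = sprintf("cycle %d %s %s", i, ch, f))
      }
    }
  }
})

test_that("features transform correctly under channel rescaling", {
  linear <- c("rms", "mad", "max_abs", "min_abs", "range", "median_abs")
  quadratic <- c("variance", "ec")
  shape <- c("skewness", "kurtosis")
  for (seed in 1:15) {
    x <- withr::with_seed(seed, rnorm(60, mean = 1))
    cc <- withr::with_seed(seed + 100, runif(1, 0.3, 4))
    for (f in linear)
      expect_equal(featureValue(cc * x, f), cc * featureValue(x, f),
                   tolerance = 1e-10)
    for (f in quadratic)
      expect_equal(featureValue(cc * x, f), cc^2 * featureValue(x, f),
                   tolerance = 1e-10)
    for (f in shape)
      expect_equal(featureValue(cc * x, f), featureValue(x, f),
                   tolerance = 1e-8)
  }
})

test_that("window means average per-cycle values arithmetically", {
  d <- matrix(0, 100, 9, dimnames = list(NULL, imuChannels()))
  d[1:50, ] <- 2
  d[51:100, ] <- 4
  w <- ImuRecording(d, sampleRate = 50)
  cyc <- data.frame(start = c(1L, 51L), end = c(51L, 101L))
  m <- windowMean(perCycleFeatures(w, cyc))
  expect_equal(m["gx", "rms"], 3)
  one <- windowMean(perCycleFeatures(w, cyc[1, ]))
  expect_equal(one["gx", "rms"], 2)
  expect_error(windowMean(perCycleFeatures(w, cyc[0, ])), "no complete")
  expect_error(perCycleFeatures(w, data.frame(start = 90L, end = 120L)),
               "bounds")
})

test_that("baseline normalization produces unit baselines and exact ratios", {
  b <- matrix(2, 9, 10, dimnames = list(imuChannels(), gaitFeatures()))
  tbl <- normalizeToBaseline(list(baseline = b, min30 = b * 1.5,
                                  min60 = b * 0.5), subject = "S01")
  expect_identical(nrow(tbl), 270L)
  expect_true(all(tbl$value[tbl$window == "baseline"] == 1))
  expect_true(all(tbl$value[tbl$window == "min30"] == 1.5))
  expect_true(all(tbl$value[tbl$window == "min60"] == 0.5))

  same <- normalizeToBaseline(list(baseline = b, min30 = b, min60 = b))
  expect_true(all(same$value == 1))

  bz <- b
  bz["gz", "mad"] <- 0
  expect_message(
    tblz <- normalizeToBaseline(list(baseline = bz, min30 = b, min60 = b)),
    "zero")
  expect_true(all(is.na(
    tblz$value[tblz$channel == "gz" & tblz$feature == "mad"])))
  expect_false(anyNA(tblz$value[tblz$feature == "rms"]))
})
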