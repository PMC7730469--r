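test_that("identical seeds reproduce recordings bit for bit", {
  cfg <- gaitSimConfig(durationMin = 1, seed = 3L)
  r1 <- simulateBout(cfg)
  r2 <- simulateBout(cfg)
  expect_identical(imuData(r1), imuData(r2))
  expect_identical(r1@meta$strikes, r2@meta$strikes)
  r3 <- simulateBout(gaitSimConfig(durationMin = 1, seed = 4L))
  expect_false(identical(imuData(r1), imuData(r3)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- rnorm(3)
  set.seed(99)
  invisible(simulateBout(gaitSimConfig(durationMin = 1, seed = 3L)))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("ground-truth strike counts follow cadence and duration", {
  # 1-min bout at 1 Hz, no jitter: 61 strikes delimit 60 complete cycles
  rec <- simulateBout(cleanSimConfig(durationMin = 1))
  expect_identical(length(rec@meta$strikes), 61L)
  expect_identical(length(diff(rec@meta$strikes)), 60L)
  for (cad in c(0.8, 0.95, 1.1)) {
    rec <- simulateBout(cleanSimConfig(durationMin = 2, cadence = cad))
    expect_lte(abs((length(rec@meta$strikes) - 1) - floor(120 * cad)), 1)
  }
})

test_that("jitter-free noiseless cycles are identical within and across windows", {
  wins <- simulateWindows(cleanSimConfig(), windows = shortWindows())
  cf <- lapply(wins, function(w) perCycleFeatures(w, segmentCycles(w)))
  v <- featureValues(cf$baseline)
  # every cycle identical: zero spread of every per-cycle statistic
  expect_lt(max(apply(v, c(1, 2), function(z) diff(range(z)))), 1e-9)
  # per-cycle RMS identical across the three analysis windows
  rms <- vapply(cf, function(x) featureValues(x)["wx", "rms", 1], numeric(1))
  expect_equal(unname(diff(range(rms))), 0, tolerance = 1e-9)
})

test_that("samples respect device full-scale ranges and angle conventions", {
  tpl <- defaultChannelTemplates()
  tpl$az$offset <- 20
  tpl$wx$amp <- c(3000, 500, 100, 50)
  tpl$gz$amp <- c(500, 100, 50)
  tpl$gy$amp <- c(300, 50, 20)
  cfg <- gaitSimConfig(durationMin = 1, templates = tpl, seed = 8L)
  d <- imuData(simulateBout(cfg))
  expect_true(all(abs(d[, 1:3]) <= 16))
  expect_true(all(abs(d[, 4:6]) <= 2000))
  expect_true(all(d[, "gx"] > -180 & d[, "gx"] <= 180))
  expect_true(all(d[, "gz"] > -180 & d[, "gz"] <= 180))
  expect_true(all(d[, "gy"] >= -90 & d[, "gy"] <= 90))
})

test_that("windows-only synthesis equals extraction from the full bout", {
  for (seed in c(2L, 13L)) {
    cfg <- gaitSimConfig(durationMin = 5, seed = seed,
                         effectTimesMin = c(3, 5),
                         effects = list(fatigueEffect("gz", "amplitude_scale",
                                                      1.1, 1.3)))
    full <- simulateBout(cfg)
    wins <- simulateWindows(cfg, windows = shortWindows())
    for (w in names(wins)) {
      ext <- extractWindow(full, shortWindows()[[w]])
      expect_identical(imuData(ext), imuData(wins[[w]]))
    }
  }
})

test_that("noiseless amplitude effects are recovered exactly in window ratios", {
  cases <- list(list(ch = "gz", m = 1.2), list(ch = "wy", m = 1.5))
  for (cs in cases) {
    eff <- fatigueEffect(cs$ch, "amplitude_scale", multiplier30 = 1,
                         multiplier60 = cs$m)
    wins <- simulateWindows(cleanSimConfig(effects = list(eff)),
                            windows = shortWindows())
    tbl <- analyzeWindows(wins)$table
    pick <- function(w, f)
      tbl$value[tbl$window == w & tbl$channel == cs$ch & tbl$feature == f]
    expect_equal(pick("min60", "rms"), cs$m, tolerance = 1e-6)
    expect_equal(pick("min60", "ec"), cs$m^2, tolerance = 1e-6)
    expect_equal(pick("min60", "variance"), cs$m^2, tolerance = 1e-6)
    expect_equal(pick("min30", "rms"), 1, tolerance = 1e-6)
    expect_equal(pick("baseline", "rms"), 1, tolerance = 1e-12)
  }
})

test_that("cycle-variability effects widen the across-cycle spread", {
  eff <- fatigueEffect("gz", "cycle_variability_scale", multiplier30 = 1,
                       multiplier60 = 4)
  cfg <- gaitSimConfig(durationMin = 5, ampCv = 0.05,
                       noiseSd = setNames(rep(0, 9), imuChannels()),
                       effects = list(eff), effectTimesMin = c(3, 5),
                       seed = 21L)
  wins <- simulateWindows(cfg, windows = shortWindows())
  spread <- vapply(wins, function(w) {
    v <- featureValues(perCycleFeatures(w, segmentCycles(w)))
    sd(v["gz", "rms", ])
  }, numeric(1))
  expect_gt(spread[["min60"]] / spread[["baseline"]], 1.5)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(gaitSimConfig(durationMin = -1), "duration")
  expect_error(gaitSimConfig(cadence = 0), "cadence")
  expect_error(gaitSimConfig(cadenceJitterCv = -0.1), "cadenceJitterCv")
  expect_error(fatigueEffect("gz", "amplitude_scale", multiplier60 = 0),
               "multipliers")
  expect_error(fatigueEffect("qq", "amplitude_scale"), "channel")
})
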