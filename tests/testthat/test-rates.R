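test_that("foci per division reproduces hand arithmetic over colonies", {
  zero <- lapply(1:4, function(i) makeTrace(0, 50, paste0("z", i)))
  fz <- fociPerDivision(zero)
  expect_equal(fz$f, 0)
  expect_equal(fz$fSem, 0)

  ## (1 focus / 100 div) x 3 colonies and (2/100) x 3: mean 0.015,
  ## SEM = sd(c(.01,.01,.01,.02,.02,.02))/sqrt(6) = 0.002236
  six <- c(lapply(1:3, function(i) makeTrace(1, 100, paste0("a", i))),
           lapply(1:3, function(i) makeTrace(2, 100, paste0("b", i))))
  fs <- fociPerDivision(six)
  expect_equal(fs$f, 0.015)
  expect_equal(fs$fSem, 0.0022360680, tolerance = 1e-6)
  expect_equal(fs$nColonies, 6L)

  ## founder-never-divided colonies are excluded with a warning
  expect_warning(fx <- fociPerDivision(c(six, list(makeTrace(0, 0, "dead")))),
                 "zero divisions")
  expect_equal(fx$f, 0.015)
  expect_equal(fx$nExcluded, 1L)
  expect_error(suppressWarnings(fociPerDivision(list(makeTrace(0, 0, "d")))),
               "no colony")
})

test_that("efficiency correction matches the published rate arithmetic", {
  ## 0.0145 / 0.71 = 0.0204 (printed 0.021); 0.006 / 0.71 = 0.00845
  r <- correctRate(0.0145, 0.006, p = 0.71)
  expect_equal(dsbRate(r), 0.0145 / 0.71)
  expect_equal(round(dsbRate(r), 3), 0.020)
  expect_lt(abs(dsbRate(r) - 0.021) / 0.021, 0.05)
  expect_equal(r@rSem, 0.006 / 0.71)
  expect_equal(round(r@rSem, 3), 0.008)

  ## p = 1 is the identity; full propagation only widens the error
  expect_equal(dsbRate(correctRate(0.0145, 0.006, p = 1)), 0.0145)
  full <- correctRate(0.0145, 0.006, p = 0.71, pSem = 0.05,
                      propagateEfficiency = TRUE)
  expect_gt(full@rSem, r@rSem)
  expect_error(correctRate(0.01, 0, p = 0), "p")

  ## pooled Wilson interval contains the pooled proportion
  est <- correctRate(0.015, 0.002, p = 0.71, totalFoci = 9,
                     totalDivisions = 600)
  expect_true(est@qCI[1] <= est@pooledQ && est@pooledQ <= est@qCI[2])
})

test_that("legacy frequency conversion is linear and exact", {
  expect_equal(frequencyToRate(0.01, 108, 98), 0.01 * 108 / 98)
  expect_equal(round(frequencyToRate(0.01, 108, 98), 3), 0.011)
  expect_equal(frequencyToRate(0.05, 70, 70), 0.05)   # one focus per cell
  expect_equal(frequencyToRate(0.02, 200, 100), 0.04)
  expect_error(frequencyToRate(0.01, 10, 0), "focusCells")
  ## linear in F and in the per-cell multiplicity
  expect_equal(frequencyToRate(0.03, 108, 98), 3 * frequencyToRate(0.01, 108, 98))
  expect_equal(frequencyToRate(0.01, 216, 98), 2 * frequencyToRate(0.01, 108, 98))
})

test_that("generation-dependence holds at fixed q and fails for clock-like foci", {
  ## same q across the growth regime and the >10x slower starvation regime
  p <- SimParams(r = 0.15, p = 1)   # default schedule: tau 1.95 h, then 26 h
  trs <- lapply(1:25, function(s) simulateMicrocolony(p, 27, seed = 100 + s))
  gd <- generationDependence(trs, boundaries = 9)
  expect_false(any(gd$regimes$flagged))
  expect_true(gd$perDivisionRatio$lo[1] <= 1 && gd$perDivisionRatio$hi[1] >= 1)
  expect_true(gd$perHourRatio$hi[1] < 1)   # per-hour rate drops when starved
  expect_true(isTRUE(gd$supported))

  ## alternative generator: foci at a fixed rate per cell-hour while the
  ## division rate drops >10-fold -- the per-division ratio must exclude 1
  alt <- lapply(1:25, function(s)
    simulateMicrocolony(SimParams(r = 0, p = 1), 27, focusModel = "time",
                        fociPerHour = 0.05, seed = 200 + s))
  gdAlt <- generationDependence(alt, boundaries = 9)
  expect_true(gdAlt$perDivisionRatio$lo[1] > 1)
  expect_false(isTRUE(gdAlt$supported))

  ## zero-foci trace: rates zero, ratio undefined, flagged as unsupported
  none <- lapply(1:3, function(s)
    simulateMicrocolony(SimParams(r = 0, p = 1), 12, seed = s))
  gd0 <- generationDependence(none, boundaries = 6)
  expect_true(all(gd0$regimes$foci == 0))
  expect_true(all(gd0$regimes$perDivision == 0 |
                    is.na(gd0$regimes$perDivision)))
  expect_true(is.na(gd0$perDivisionRatio$lo[1]))
  expect_true(is.na(gd0$supported) || !gd0$supported)

  expect_error(generationDependence(trs, boundaries = c(40)), "interior")
})

test_that("the exposure-control comparison has coverage and power", {
  x <- rep(c(0, 1), c(90, 10))
  same <- exposureControlCompare(x, x)
  expect_equal(same$difference, 0)

  ## coverage: two samples at the same q, 100 replicates
  set.seed(7)
  cover <- 0L
  for (k in 1:100) {
    a <- rbinom(500, 1, 0.05)
    b <- rbinom(500, 1, 0.05)
    cc <- exposureControlCompare(a, b)
    if (cc$ci[1] <= 0 && 0 <= cc$ci[2]) cover <- cover + 1L
  }
  expect_gte(cover, 90L)

  ## power: q vs 3q at n = 500
  set.seed(8)
  reject <- 0L
  for (k in 1:100) {
    a <- rbinom(500, 1, 0.02)
    b <- rbinom(500, 1, 0.06)
    cc <- exposureControlCompare(a, b)
    if (cc$ci[1] > 0 || cc$ci[2] < 0) reject <- reject + 1L
  }
  expect_gte(reject, 90L)

  ## degenerate unequal constants are flagged, not silently intervalled
  flag <- exposureControlCompare(rep(0, 5), rep(1, 5))
  expect_true(flag$flagged)
  expect_true(all(is.na(flag$ci)))
})
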