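test_that("microcolony traces conserve cells, order events and are reproducible", {
  p <- SimParams(r = 0.3, p = 0.9)
  for (s in 1:5) {
    tr <- simulateMicrocolony(p, tEnd = 7, seed = s)
    fr <- frames(tr)
    expect_true(all(fr$n_cells == 1L + fr$cum_divisions))
    expect_true(all(diff(fr$cum_divisions) >= 0))
    expect_true(all(diff(fr$cum_foci) >= 0))
    ## arrest: no cell divides after its focus event
    ev <- events(tr)
    for (cid in ev$cell_id[ev$kind == "focus"]) {
      tFoc <- min(ev$time_h[ev$kind == "focus" & ev$cell_id == cid])
      expect_true(all(ev$time_h[ev$kind == "division" &
                                  ev$cell_id == cid] <= tFoc))
    }
  }
  a <- simulateMicrocolony(p, tEnd = 7, seed = 11)
  b <- simulateMicrocolony(p, tEnd = 7, seed = 11)
  expect_identical(frames(a), frames(b))
  expect_identical(events(a), events(b))
})

test_that("zero break rate gives zero foci; certain breakage marks every division", {
  p0 <- SimParams(r = 0, p = 1)
  tr <- simulateMicrocolony(p0, tEnd = 10, seed = 1)
  expect_true(all(frames(tr)$cum_foci == 0L))

  ## q = 1 with arrest: every division yields a focus on one daughter, which
  ## never divides again, so the colony grows as a chain with
  ## cum_foci == cum_divisions at all times
  p1 <- SimParams(r = 1, p = 1, arrestOnFocus = TRUE,
                  tauSchedule = data.frame(start_h = 0, tau_h = 1))
  tr1 <- simulateMicrocolony(p1, tEnd = 8, seed = 2)
  fr <- frames(tr1)
  expect_gt(fr$cum_divisions[nrow(fr)], 0L)
  expect_identical(fr$cum_foci, fr$cum_divisions)
  ev <- events(tr1)
  for (cid in ev$cell_id[ev$kind == "focus"]) {
    tFoc <- ev$time_h[ev$kind == "focus" & ev$cell_id == cid]
    expect_true(all(ev$time_h[ev$kind == "division" &
                                ev$cell_id == cid] <= tFoc))
  }
})

test_that("foci per division recovers q = r*p (Bernoulli thinning oracle)", {
  ## oracle: each division is an independent Bernoulli(q) trial, so the
  ## pooled foci/divisions ratio has mean q and SE sqrt(q(1-q)/n)
  q <- 0.0145
  p <- SimParams(r = q, p = 1)
  trs <- lapply(1:250, function(s) simulateMicrocolony(p, tEnd = 9, seed = s))
  fp <- fociPerDivision(trs)
  qhat <- fp$totalFoci / fp$totalDivisions
  se <- sqrt(q * (1 - q) / fp$totalDivisions)
  expect_gt(fp$totalDivisions, 5000)
  expect_lt(abs(qhat - q), 3 * se)
})

test_that("parameter validation rejects out-of-range simulation inputs", {
  expect_error(SimParams(r = 1.5), "r must lie")
  expect_error(SimParams(p = -0.1), "p must lie")
  expect_error(SimParams(tauSchedule = data.frame(start_h = 1, tau_h = 2)),
               "start at time 0")
  expect_error(simulateMicrocolony(SimParams(), tEnd = -1), "tEnd")
  expect_error(simulateDoseResponse(SimParams(), numeric(0), 10), "non-empty")
  expect_error(simulateDoseResponse(SimParams(), c(0, NA), 10), "finite")
  expect_error(simulateDoseResponse(SimParams(), c(0, 10), 0), "nCells")
})

test_that("dose-response means follow the Poisson-thinning closed form", {
  ## y = 0, b = 0: no foci at any dose
  z <- simulateDoseResponse(SimParams(y = 0, b = 0), c(0, 50, 140), 500,
                            seed = 1)
  expect_true(all(z$mean_foci == 0))

  ## p = 1, b = 0: mean foci at dose D ~ Poisson mean y*D
  p <- SimParams(y = 0.031, p = 1, b = 0)
  n <- 10000
  tab <- simulateDoseResponse(p, c(40, 140), n, seed = 2)
  for (i in 1:2) {
    D <- tab$dose_Gy[i]
    se <- sqrt(0.031 * D / n)
    expect_lt(abs(tab$mean_foci[i] - 0.031 * D), 3 * se)
    ## thinning preserves the Poisson mean = variance identity
    expect_lt(abs(tab$sd_foci[i]^2 - 0.031 * D),
              4 * 0.031 * D * sqrt(2 / n) + 0.01)
  }

  ## study condition: 0.043 + 0.71 * 0.031 * 140 = 3.1243 foci/cell at 140 Gy
  tab2 <- simulateDoseResponse(SimParams(), c(140), 10000, seed = 3)
  se2 <- sqrt((0.71 * 0.031 * 140 + 0.043 * 0.957) / 10000)
  expect_lt(abs(tab2$mean_foci - 3.1243), 3 * se2)
})

test_that("cut-focus counts match the exact binomial-mixture enumeration", {
  one <- simulateCutFoci(CopyModel(copies = 1L, prob = 1, cutProb = 1),
                         p = 1, nCells = 100, seed = 1)
  expect_true(all(one == 1L))
  two <- simulateCutFoci(CopyModel(copies = 2L, prob = 1, cutProb = 1),
                         p = 1, nCells = 100, seed = 1)
  expect_true(all(two > 1L))

  ## oracle: exact enumeration over copy number and binomial outcomes,
  ## per-copy success 0.8 * 0.8 = 0.64 on copies uniform {2, 4}
  pc <- 0.64
  exact <- mean(sapply(c(2, 4), function(k)
    1 - dbinom(0, k, pc) - dbinom(1, k, pc)))
  n <- 50000
  sim <- simulateCutFoci(CopyModel(copies = c(2L, 4L), prob = c(0.5, 0.5),
                                   cutProb = 0.8), p = 0.8, nCells = n,
                         seed = 4)
  se <- sqrt(exact * (1 - exact) / n)
  expect_lt(abs(mean(sim > 1) - exact), 3 * se)
})

test_that("focus-pair displacements follow the saturating distance curve", {
  ## zero genomic distance: exact overlap
  fp0 <- simulateFocusPairs(0, nCells = 50, seed = 1)
  g <- fp0[fp0$channel == "green", ]
  r <- fp0[fp0$channel == "red", ]
  expect_equal(g$x_um, r$x_um)
  expect_equal(g$y_um, r$y_um)

  ## far separation: sample mean displacement at the plateau (0.57 um)
  n <- 10000
  fp <- simulateFocusPairs(2400, nCells = n, plateau = 0.57, seed = 2)
  g <- fp[fp$channel == "green", ]
  r <- fp[fp$channel == "red", ]
  d <- sqrt((g$x_um - r$x_um)^2 + (g$y_um - r$y_um)^2)
  sig <- 0.57 * sqrt(2 / pi)
  se <- sqrt((2 - pi / 2) * sig^2 / n)   # Rayleigh sd / sqrt(n)
  expect_lt(abs(mean(d) - 0.57), 3 * se)

  ## monotone in genomic distance
  meanDisp <- function(kb, seed) {
    fp <- simulateFocusPairs(kb, nCells = 4000, seed = seed)
    g <- fp[fp$channel == "green", ]
    r <- fp[fp$channel == "red", ]
    mean(sqrt((g$x_um - r$x_um)^2 + (g$y_um - r$y_um)^2))
  }
  m <- sapply(c(10, 55, 80), meanDisp, seed = 3)
  expect_true(all(diff(m) > 0))
  expect_error(simulateFocusPairs(-5, 10), "genomicDistanceKb")
})

test_that("rendered images have Gaussian-spot photon statistics", {
  empty <- ImageScene(shape = c(16, 16), pixelSize = 0.1, background = 0)
  expect_true(all(renderImage(empty, seed = 1) == 0))

  sc <- ImageScene(shape = c(32, 32), pixelSize = 0.1,
                   spots = data.frame(x_um = 1.52, y_um = 1.47,
                                      amplitude = 1000, sigma_um = 0.1),
                   background = 10)
  ## brightest pixel lands within 1 pixel of the spot centre
  hits <- 0L
  tot <- numeric(200)
  for (s in 1:200) {
    img <- renderImage(sc, seed = s)
    ij <- which(img == max(img), arr.ind = TRUE)[1, ]
    if (abs(ij[1] - 1 - 14.7) <= 1 && abs(ij[2] - 1 - 15.2) <= 1) {
      hits <- hits + 1L
    }
    tot[s] <- sum(img)
  }
  expect_gte(hits / 200, 0.99)
  ## total photons: background * n_pixels + amplitude * 2*pi*(sigma/px)^2
  expected <- 10 * 32 * 32 + 1000 * 2 * pi * 1
  se <- sqrt(expected / 200)   # Poisson total, averaged over seeds
  expect_lt(abs(mean(tot) - expected), 4 * se)

  expect_error(ImageScene(shape = c(16, 16), pixelSize = 0.1,
                          spots = data.frame(x_um = 5, y_um = 0.5,
                                             amplitude = 10, sigma_um = 0.1),
                          background = 0),
               "inside the field")
  expect_identical(renderImage(sc, seed = 7), renderImage(sc, seed = 7))
})

test_that("foci per division is schedule-invariant while foci per hour is not", {
  ## the computational analogue of varying the division rate: same q, fast
  ## vs starved schedules give the same per-division rate but different
  ## per-hour rates
  q <- 0.1
  fast <- SimParams(r = q, p = 1,
                    tauSchedule = data.frame(start_h = 0, tau_h = 1))
  slow <- SimParams(r = q, p = 1,
                    tauSchedule = data.frame(start_h = 0, tau_h = 4))
  fTr <- lapply(1:40, function(s) simulateMicrocolony(fast, 6, seed = s))
  sTr <- lapply(1:40, function(s) simulateMicrocolony(slow, 24, seed = 1000 + s))
  fpF <- suppressWarnings(fociPerDivision(fTr))
  fpS <- suppressWarnings(fociPerDivision(sTr))
  qF <- fpF$totalFoci / fpF$totalDivisions
  qS <- fpS$totalFoci / fpS$totalDivisions
  seDiff <- sqrt(q * (1 - q) * (1 / fpF$totalDivisions +
                                  1 / fpS$totalDivisions))
  expect_lt(abs(qF - qS), 4 * seDiff)
  ## per-hour rates differ by ~ the 4-fold division-rate ratio
  hrF <- fpF$totalFoci / (40 * 6)
  hrS <- fpS$totalFoci / (40 * 24)
  expect_gt(hrF / hrS, 2)
})
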