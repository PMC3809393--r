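cell1 <- function(gx, gy, rx, ry, cid = 1) {
  rbind(data.frame(cell_id = cid, channel = "green", x_um = gx, y_um = gy,
                   intensity = 1),
        data.frame(cell_id = cid, channel = "red", x_um = rx, y_um = ry,
                   intensity = 1))
}

test_that("per-cell matching classifies ratio classes and distances", {
  ## coincident 1:1 pair
  m <- matchFoci(cell1(1, 1, 1, 1))
  expect_equal(m$pairs$ratio_class, "1:1")
  expect_equal(m$pairs$distance_um, 0)

  ## one green, two red at 0.57 and 0.84 um: 1:2 with near/far split
  m2 <- matchFoci(cell1(0, 0, c(0.57, -0.84), c(0, 0)))
  expect_equal(m2$cells$ratio_class, "1:2")
  expect_equal(m2$cells$near_um, 0.57)
  expect_equal(m2$cells$far_um, 0.84)

  ## empty-channel cells are excluded and counted
  calls <- rbind(cell1(1, 1, 1, 1, cid = 1),
                 data.frame(cell_id = 2, channel = "red", x_um = 0, y_um = 0,
                            intensity = 1))
  m3 <- matchFoci(calls)
  expect_equal(m3$nExcluded, 1L)
  expect_equal(nrow(m3$cells), 1L)
})

test_that("matching equals brute-force minimum-total-distance assignment", {
  set.seed(31)
  for (rep in 1:40) {
    ng <- sample(1:6, 1)
    nr <- sample(1:6, 1)
    calls <- rbind(
      data.frame(cell_id = 1, channel = "green", x_um = runif(ng, 0, 3),
                 y_um = runif(ng, 0, 1), intensity = 1),
      data.frame(cell_id = 1, channel = "red", x_um = runif(nr, 0, 3),
                 y_um = runif(nr, 0, 1), intensity = 1))
    m <- matchFoci(calls)
    g <- calls[calls$channel == "green", ]
    r <- calls[calls$channel == "red", ]
    D <- distMat(g, r)
    if (ng <= nr) oracle <- bruteAssignCost(D) else
      oracle <- bruteAssignCost(t(D))
    expect_equal(sum(m$pairs$distance_um), oracle, tolerance = 1e-10)
  }
})

test_that("matching is symmetric under channel relabelling", {
  set.seed(32)
  calls <- rbind(
    data.frame(cell_id = rep(1:5, each = 2), channel = "green",
               x_um = runif(10, 0, 3), y_um = runif(10, 0, 1), intensity = 1),
    data.frame(cell_id = rep(1:5, each = 2), channel = "red",
               x_um = runif(10, 0, 3), y_um = runif(10, 0, 1), intensity = 1))
  m1 <- matchFoci(calls)
  swapped <- calls
  swapped$channel <- ifelse(calls$channel == "green", "red", "green")
  m2 <- matchFoci(swapped)
  expect_equal(sort(m1$pairs$distance_um), sort(m2$pairs$distance_um))
})

test_that("colocalization fraction counts overlaps and grows with threshold", {
  ## 10 cells: 8 pairs at 0.05 um, 2 at 0.30 um; threshold 0.2 -> 80%
  calls <- do.call(rbind, c(
    lapply(1:8, function(i) cell1(0, 0, 0.05, 0, cid = i)),
    lapply(9:10, function(i) cell1(0, 0, 0.30, 0, cid = i))))
  m <- matchFoci(calls)
  cf <- colocalizationFraction(m, thresholdUm = 0.2)
  expect_equal(cf$pct, 80)
  expect_equal(cf$nCells, 10L)

  ## monotone non-decreasing in the threshold
  fp <- simulateFocusPairs(55, nCells = 300, seed = 6)
  mm <- matchFoci(fp)
  pcts <- sapply(c(0.05, 0.1, 0.2, 0.4, 0.8),
                 function(th) colocalizationFraction(mm, th)$pct)
  expect_true(all(diff(pcts) >= 0))

  ## generator property: zero genomic distance overlaps at any threshold
  f0 <- matchFoci(simulateFocusPairs(0, nCells = 100, seed = 7))
  expect_equal(colocalizationFraction(f0, 0.01)$pct, 100)

  ## SEM across experiment labels
  cfE <- colocalizationFraction(m, 0.2, experiment = rep(1:2, 5))
  expect_true(cfE$sem >= 0)
  expect_error(colocalizationFraction(matchFoci(cell1(0, 0, c(1, 2), c(0, 0))),
                                      0.2), "no 1:1")
})

test_that("interfocal summary separates 1:1 from 1:2 near/far populations", {
  single <- matchFoci(cell1(0, 0, 0.3, 0.4))   # distance 0.5
  s1 <- interfocalSummary(single)
  expect_equal(s1$mean_1to1_um, 0.5)
  expect_true(is.na(s1$mean_near_um))          # empty class absent, not zero

  mixed <- matchFoci(rbind(
    cell1(0, 0, 0.2, 0, cid = 1),                      # 1:1 at 0.2
    cell1(0, 0, 0.6, 0, cid = 2),                      # 1:1 at 0.6
    cell1(0, 0, c(0.5, -0.9), c(0, 0), cid = 3)))      # 1:2 near .5 far .9
  s <- interfocalSummary(mixed)
  expect_equal(s$mean_1to1_um, 0.4)
  expect_equal(s$mean_near_um, 0.5)
  expect_equal(s$mean_far_um, 0.9)
  expect_equal(s$n_1to1, 2L)
  expect_equal(s$n_1to2, 1L)

  ## generator property: 1:1 distance non-decreasing in genomic separation
  means <- sapply(c(10, 80, 2400), function(kb)
    interfocalSummary(matchFoci(simulateFocusPairs(kb, 2000,
                                                   seed = 8)))$mean_1to1_um)
  expect_true(all(diff(means) > 0))
})

test_that("category counting supports both documented denominators", {
  a <- data.frame(x_um = 1:3, y_um = 0)
  expect_equal(categoryCounts(a, a, 0.2)$pctBoth, 100)

  b <- data.frame(x_um = 1:2 + 100, y_um = 0)
  disj <- categoryCounts(a, b, 0.2)
  expect_equal(disj$pctBoth, 0)
  expect_equal(disj$pctAonly, 100 * 3 / 5)
  expect_equal(disj$pctBonly, 100 * 2 / 5)

  ## 10 vs 10 with exactly 4 coincident: pairs denominator 4/16 = 25%,
  ## per-focus denominator 8/20 = 40%
  A <- data.frame(x_um = seq(0, 9), y_um = 0)
  B <- data.frame(x_um = c(seq(0, 3) + 0.01, seq(20, 25)), y_um = 0)
  pr <- categoryCounts(A, B, 0.2, denominator = "pairs")
  expect_equal(pr$nBoth, 4L)
  expect_equal(pr$pctBoth, 25)
  expect_equal(pr$pctAonly, 100 * 6 / 16)
  fo <- categoryCounts(A, B, 0.2, denominator = "foci")
  expect_equal(fo$pctBoth, 40)

  ## symmetry: swapping channels swaps the single-channel classes
  sw <- categoryCounts(B, A, 0.2, denominator = "pairs")
  expect_equal(sw$pctBoth, pr$pctBoth)
  expect_equal(sw$pctAonly, pr$pctBonly)
  expect_error(categoryCounts(a[0, ], b[0, ], 0.2), "empty")
})

test_that("green-per-red ratio estimates per-chromosome detection", {
  expect_equal(greenPerRed(c(1, 1, 1), c(1, 1, 1)), 1)
  ## 82 green foci among 100 red-marked chromosomes
  expect_equal(greenPerRed(rep(c(1, 0), c(82, 18)), rep(1, 100)), 0.82)
  ## cells without red foci are excluded from the ratio
  expect_equal(greenPerRed(c(1, 5), c(1, 0)), 1)
  expect_error(greenPerRed(c(1, 1), c(0, 0)), "no cells")

  ## fully cut, fully labelled chromosomes with detection 0.82: the ratio is
  ## a binomial proportion with mean 0.82
  n <- 20000
  green <- simulateCutFoci(CopyModel(copies = 1L, prob = 1, cutProb = 1),
                           p = 0.82, nCells = n, seed = 9)
  ratio <- greenPerRed(green, rep(1L, n))
  expect_lt(abs(ratio - 0.82), 3 * sqrt(0.82 * 0.18 / n))
})
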