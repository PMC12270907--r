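test_that("Gaussian smoothing preserves constants and vector length", {
  x <- rep(3.5, 100)
  expect_equal(gaussianSmooth(x, 5), x)
  set.seed(1)
  y <- rnorm(200)
  expect_length(gaussianSmooth(y, 5), 200)
  expect_lt(sd(gaussianSmooth(y, 5)), sd(y))
})

test_that("binary segmentation matches the exhaustive least-squares oracle", {
  set.seed(2)
  for (rep in 1:5) {
    pos <- sample(150:450, 1)
    x <- c(rep(0, pos), rep(1, 600 - pos)) + rnorm(600, 0, 0.05)
    an <- detectAnchors(x, sigma = 5)
    expect_lte(abs(an$startChange - oracleBestBreak1(x)), 10)
    expect_lte(abs(an$startChange - pos), 10)
  }
  # two planted breaks: ramp up then down
  for (rep in 1:5) {
    b <- sort(sample(c(150:250, 350:450), 2))
    x <- c(rep(0, b[1]), rep(1, b[2] - b[1]), rep(0.1, 600 - b[2])) +
      rnorm(600, 0, 0.05)
    an <- detectAnchors(x, sigma = 5)
    orc <- oracleBestBreak2(x)
    expect_lte(abs(an$startChange - orc[1]), 10)
    expect_lte(abs(an$endChange - orc[2]), 10)
  }
})

test_that("flat vectors yield an explicit null anchor call", {
  an <- detectAnchors(rep(2, 600))
  expect_true(an$null)
  expect_true(is.na(an$startChange))
  expect_true(is.na(an$endChange))
  expect_error(detectAnchors(rnorm(10), sigma = 5), "4 x sigma")
})

test_that("window averages cover the requested cells around a change point", {
  x <- c(rep(0, 300), rep(1, 300))
  an <- detectAnchors(x, sigma = 5, nUp = 75, nDown = 10)
  w <- an$windows[an$windows$change == an$startChange, ]
  expect_equal(w$upstreamMean, mean(x[(w$change - 74):w$change]))
  expect_equal(w$downstreamMean, mean(x[(w$change + 1):(w$change + 10)]))
  expect_equal(w$symUpMean, mean(x[(w$change - 49):w$change]))
})

test_that("ordered averages equal brute-force row means after ordering", {
  set.seed(3)
  m <- matrix(rnorm(50 * 4), 50)
  ord <- runif(50)
  expect_equal(orderAverage(m, ord), rowMeans(m)[order(ord)])
  # single-bin feature: the ordered bin values themselves
  m1 <- m[, 1, drop = FALSE]
  expect_equal(orderAverage(m1, ord), m[order(ord), 1])
  expect_error(orderAverage(m[, 0, drop = FALSE], ord), "no bins")
})

test_that("anchor position recovers the planted growth origin", {
  g <- fixtureGenome()
  for (anchor in c(2L, 5L, 9L)) {
    tr <- makeSimTruth(g, nCells = 600, nFeatures = 1, binsPerFeature = 9,
                       contactProb = 1, anchorOffset = anchor,
                       switchTime = 0.7, cellTimes = sort(runif(600)),
                       seed = anchor)
    occ <- simulateOccupancy(tr, dynamics = TRUE, seed = anchor)
    ap <- anchorPosition(t(occ$damid$binary))
    expect_identical(ap$anchorBin, anchor)
  }
  # simultaneous establishment: tie broken to the leftmost bin and flagged
  m <- matrix(rep(c(rep(0, 300), rep(1, 300)), each = 5), nrow = 5)
  ap2 <- anchorPosition(m)
  expect_identical(ap2$anchorBin, 1L)
  expect_true(ap2$tie)
  expect_error(anchorPosition(m[1:2, ]), "3 bins")
})

test_that("noiseless cells along one trajectory are ordered exactly", {
  p <- kineticParams(1, 1, 0.7, 4)
  tt <- seq(0.2, 7.6, length.out = 40)
  tr <- kineticTrajectory(tt, p)
  st <- fitLatentTime(matrix(tr$u, ncol = 1), matrix(tr$s, ncol = 1))
  ft <- latentTime(st, consensus = FALSE)[, 1]
  expect_equal(cor(ft, tt, method = "spearman"), 1)
})

test_that("identical cells collapse to a degenerate latent time", {
  u <- matrix(0.5, 20, 2); s <- matrix(0.3, 20, 2)
  st <- fitLatentTime(u, s)
  expect_true(st@degenerate)
  expect_true(all(latentTime(st) == latentTime(st)[1]))
})

test_that("noisy simulations are recovered and shuffled pairing destroys order", {
  sim <- simulateKinetics(kineticParams(1, 1, 0.7, 4), nCells = 300,
                          noiseSd = 0.05, nFeatures = 20, seed = 11)
  st <- fitLatentTime(sim$u, sim$s, seed = 11)
  expect_gte(cor(latentTime(st), sim$trueTime, method = "spearman"), 0.8)
  # negative control: each cell keeps its past-state (s) profile but
  # receives a random cell's present-state (u) profile
  set.seed(99)
  st2 <- fitLatentTime(sim$u[sample(300), ], sim$s, seed = 11)
  expect_lt(abs(cor(latentTime(st2), sim$trueTime, method = "spearman")),
            0.35)
})

test_that("velocity sign tracks the true kinetic phase", {
  sim <- simulateKinetics(kineticParams(1, 1, 0.7, 4), nCells = 300,
                          noiseSd = 0.05, nFeatures = 10, seed = 12)
  st <- fitLatentTime(sim$u, sim$s, seed = 12)
  v <- velocityField(st)
  truePhase <- ifelse(sim$trueTime < 4, 1, -1)
  agree <- mean(sign(v) == truePhase)
  expect_gte(agree, 0.9)
})

test_that("latent-time coupling decays with genomic distance", {
  # identical time vectors correlate at 1
  ft <- matrix(runif(100), 100, 2,
               dimnames = list(NULL, c("f1", "f2")))
  coords <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 2e6), width = 1e5))
  dd <- timeDistanceDecay(ft, coords)
  expect_equal(dd$r, 1)
  # independent features: mean r near 0
  set.seed(13)
  ftI <- matrix(runif(100 * 8), 100,
                dimnames = list(NULL, sprintf("f%d", 1:8)))
  coordsI <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = (1:8) * 1e6, width = 1e5))
  ddI <- timeDistanceDecay(ftI, coordsI)
  expect_lt(abs(mean(ddI$r)), 0.2)
  # planted exponential coupling decay: rolling mean decreases with distance
  set.seed(14)
  pos <- (1:10) * 1e6
  K <- exp(-as.matrix(dist(pos)) / 3e6)
  L <- chol(K)
  tm <- matrix(rnorm(200 * 10), 200) %*% L
  colnames(tm) <- sprintf("f%d", 1:10)
  coordsD <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = pos, width = 1e5))
  ddD <- timeDistanceDecay(tm, coordsD, rollWidth = 9)
  rr <- ddD$rollingR[!is.na(ddD$rollingR)]
  expect_gt(mean(head(rr, 5)), mean(tail(rr, 5)))
  # constant time vectors are skipped
  ftC <- cbind(ft, f3 = rep(0.5, 100))
  ddC <- timeDistanceDecay(ftC, c(coords, coordsI[1]))
  expect_false(any(ddC$featureA == "f3" | ddC$featureB == "f3"))
})
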