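bins100k <- function(n = 50) {
  GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = (seq_len(n) - 1) * 1e5 + 1, width = 1e5))
}

test_that("binarization thresholds log2(OE) at 1 (OE >= 2)", {
  m <- matrix(c(2.0, 1.99, 0, 4.7), 1)
  b <- binarize(m)
  expect_identical(unname(occupancy(b)[1, ]), c(1L, 0L, 0L, 1L))
  # configurable threshold
  b2 <- binarize(m, thresholdLog2 = 2)
  expect_identical(unname(occupancy(b2)[1, ]), c(0L, 0L, 0L, 1L))
  # masked bins are 0 with the mask retained
  mNA <- matrix(c(4, NA), 1)
  bNA <- binarize(mNA)
  expect_identical(unname(occupancy(bNA)[1, ]), c(1L, 0L))
  expect_identical(unname(occupancyMask(bNA)[1, ]), c(FALSE, TRUE))
})

test_that("contact frequency is the per-feature positive-cell fraction", {
  m <- matrix(0L, 10, 3)
  m[, 1] <- 1L
  m[1:3, 2] <- 1L
  expect_equal(unname(contactFrequency(m)), c(1, 0.3, 0))
  # invariant to cell permutation
  expect_equal(contactFrequency(m[sample(10), ]), contactFrequency(m))
  expect_error(contactFrequency(m[0, , drop = FALSE]), "one cell")
})

test_that("bulk LAD calling merges across small gaps before size filtering", {
  gr <- bins100k()
  oe <- rep(0.5, 50)
  oe[11:12] <- 3                     # 200 kb isolated: dropped
  oe[21:23] <- 3; oe[25:27] <- 3     # 300 + 300 kb bridged by 100 kb: one LAD
  oe[31:33] <- 3; oe[36:38] <- 3     # separated by 200 kb: two LADs
  ds <- callLadsBulk(oe, gr)
  df <- as.data.frame(domains(ds))
  expect_equal(nrow(df), 3)
  expect_equal(df$start, c(2000001, 3000001, 3500001))
  expect_equal(df$width, c(700000, 300000, 300000))
  # two 200-kb runs 100 kb apart survive as one 500-kb LAD (merge first)
  oe2 <- rep(0.5, 50); oe2[5:6] <- 3; oe2[8:9] <- 3
  ds2 <- callLadsBulk(oe2, gr)
  expect_equal(GenomicRanges::width(domains(ds2)), 500000)
})

test_that("bulk LAD calling is idempotent on its own indicator track", {
  gr <- bins100k()
  oe <- rep(0.5, 50); oe[10:14] <- 4; oe[30:36] <- 4
  ds <- callLadsBulk(oe, gr)
  ind <- rep(0.5, 50)
  hits <- GenomicRanges::findOverlaps(gr, domains(ds))
  ind[S4Vectors::queryHits(hits)] <- 4
  ds2 <- callLadsBulk(ind, gr)
  expect_identical(as.data.frame(domains(ds)), as.data.frame(domains(ds2)))
})

test_that("consensus keeps only domains identified by both readouts", {
  mk <- function(starts, ends) {
    methods::new("DomainSet", ranges = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = starts, end = ends)), minSize = 3e5)
  }
  a <- mk(1, 500000)
  expect_identical(as.data.frame(domains(consensusDomains(a, a))),
                   as.data.frame(domains(a)))
  b <- mk(700001, 1100000)
  expect_length(domains(consensusDomains(a, b)), 0)
  # partial overlap [0, 500 kb) x [300 kb, 800 kb): 200 kb < min size
  c <- mk(300001, 800000)
  expect_length(domains(consensusDomains(a, c)), 0)
  expect_length(domains(consensusDomains(a, c, minSize = 1e5)), 1)
  expect_equal(GenomicRanges::width(
    domains(consensusDomains(a, c, minSize = 1e5))), 200000)
  # union mode spans both members of an overlapping pair
  u <- consensusDomains(a, c, mode = "union")
  expect_equal(GenomicRanges::width(domains(u)), 800000)
})

test_that("single-cell LAD calls use mean-then-log over domain bins", {
  gr <- bins100k(6)
  doms <- methods::new("DomainSet", ranges = GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = 1, end = 2e5)), minSize = 0)
  oeM <- methods::new("OEMatrix",
    oe = rbind(all2 = c(2, 2, 0, 0, 0, 0),
               mixed = c(3, 1, 0, 0, 0, 0),     # mean 2: present
               low = c(1.5, 1.5, 0, 0, 0, 0),   # mean 1.5: absent
               masked = c(NA, NA, 0, 0, 0, 0)),
    bins = gr, mask = rep(FALSE, 6), modality = "damid",
    emptyCells = character(0))
  sc <- callLadsSc(oeM, doms)
  expect_identical(unname(occupancy(sc)[, 1]), c(1L, 1L, 0L, 0L))
  expect_identical(unname(occupancyMask(sc)[, 1]),
                   c(FALSE, FALSE, FALSE, TRUE))
})

test_that("the combined state encoding is a bijection on \\{0,1\\}^2", {
  md <- matrix(c(1L, 0L, 1L, 0L), 2)
  mc <- matrix(c(0L, 1L, 1L, 0L), 2)
  st <- combineState(md, mc)
  expect_identical(as.vector(st), c(1L, 2L, 3L, 0L))
  dec <- decodeState(st)
  expect_identical(dec$md, md)
  expect_identical(dec$mc, mc)
  # property: round trip over random matrices
  set.seed(6)
  a <- matrix(rbinom(100, 1, 0.5), 10); b <- matrix(rbinom(100, 1, 0.5), 10)
  dec2 <- decodeState(combineState(a, b))
  expect_identical(dec2$md, matrix(as.integer(a), 10))
  expect_identical(dec2$mc, matrix(as.integer(b), 10))
  expect_error(combineState(a, b[1:5, ]), "shape")
})

test_that("sliding-window CF matches brute-force window recounts", {
  set.seed(7)
  m <- matrix(rbinom(200 * 3, 1, 0.4), 200)
  ord <- runif(200)
  sw <- slidingCf(m, ord, window = 50, step = 10)
  mo <- m[order(ord), ]
  for (w in seq_along(sw$starts)) {
    idx <- sw$starts[w]:(sw$starts[w] + 49)
    expect_equal(unname(sw$cf[w, ]), unname(colMeans(mo[idx, ])))
  }
  # constant column: all windows equal; window = n equals global CF
  mc <- matrix(1L, 200, 1)
  swc <- slidingCf(mc, ord, window = 50)
  expect_true(all(swc$cf == 1))
  swAll <- slidingCf(m, ord, window = 200)
  expect_equal(unname(swAll$cf[1, ]), unname(contactFrequency(m)))
  # column positive only in the last 100 ordered cells
  m2 <- matrix(0L, 200, 1); m2[order(ord)[101:200], 1] <- 1L
  sw2 <- slidingCf(m2, ord, window = 100)
  expect_equal(sw2$cf[1, 1], 0)
  expect_equal(sw2$cf[length(sw2$starts), 1], 1)
  # overlap track
  swo <- slidingCf(m, ord, window = 50, binary2 = m)
  expect_equal(swo$overlap, swo$cf)
  expect_error(slidingCf(m, ord, window = 500), "window")
})
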