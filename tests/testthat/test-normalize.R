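test_that("binning is half-open and matches a brute-force histogram", {
  g <- fixtureGenome()   # binSize 1000
  ev <- data.frame(cell = "c1", chrom = "chr1",
                   pos = c(1L, 1000L, 1001L), strand = "+", umi = "AAA",
                   modality = "damid", allele = "none", weight = 1L)
  b <- binEvents(ev, g)
  expect_equal(unname(b$counts[1, 1]), 2)   # positions 1 and 1000: first bin
  expect_equal(unname(b$counts[1, 2]), 1)   # position 1001: second bin
  # scattered events equal an independent per-bin recount
  set.seed(2)
  ev2 <- data.frame(cell = sample(c("c1", "c2"), 100, TRUE),
                    chrom = sample(chromNames(g), 100, TRUE),
                    pos = sample(20000L, 100), strand = "+", umi = "AAA",
                    modality = "damid", allele = "none", weight = 1L)
  b2 <- binEvents(ev2, g)
  expect_equal(unname(colSums(b2$counts)), oracleHistogram(ev2, g, 1000))
  # out-of-range event
  ev3 <- transform(ev, pos = 99999L)
  expect_error(binEvents(ev3, g), "beyond")
})

test_that("in silico DamID expectation equals 2 x motifs per bin when fully mappable", {
  g <- fixtureGenome()
  exp <- expectedDamid(g, readLen = 65)
  grid <- bins(exp)
  motifCount <- numeric(length(grid))
  for (ch in chromNames(g)) {
    for (m in gatcPositions(g)[[ch]]) {
      i <- binIndex(ch, m, grid)
      motifCount[i] <- motifCount[i] + 1
    }
  }
  expect_identical(expectedValues(exp), 2 * motifCount)
  expect_identical(binMask(exp), motifCount == 0)
})

test_that("motifs inside a planted repeat contribute nothing to the expectation", {
  g <- fixtureRepeatGenome()
  exp <- expectedDamid(g, readLen = 65)
  rr <- g@repeatRegions
  expect_length(rr, 2L)
  # motifs whose 65-nt fragments (both orientations) lie fully inside a
  # duplicated block multi-map and must contribute 0
  inRepeat <- function(m) any(m >= GenomicRanges::start(rr) + 61 &
                              m <= GenomicRanges::start(rr) + 133)
  grid <- bins(exp)
  mappable <- numeric(length(grid))
  nIn <- 0
  for (m in gatcPositions(g)$chr1) {
    if (inRepeat(m)) { nIn <- nIn + 1; next }
    i <- binIndex("chr1", m, grid)
    mappable[i] <- mappable[i] + 2
  }
  expect_gte(nIn, 2)  # one motif per repeat copy by construction
  expect_identical(expectedValues(exp), mappable)
})

test_that("the ChIC expectation is the binned control histogram", {
  g <- fixtureGenome()
  set.seed(5)
  ctrl <- data.frame(cell = "bulk", chrom = sample(chromNames(g), 2000, TRUE),
                     pos = sample(20000L, 2000, TRUE), strand = "+",
                     umi = sprintf("u%04d", 1:2000), modality = "chic",
                     allele = "none", weight = 1L)
  exp <- expectedChic(ctrl, g)
  expect_equal(expectedValues(exp), oracleHistogram(ctrl, g, 1000))
  expect_error(expectedChic(ctrl[0, ], g), "empty")
})

test_that("OE is 1 under proportionality and scales with enrichment", {
  g <- fixtureGenome()
  exp <- expectedDamid(g)
  vals <- expectedValues(exp)
  unmasked <- which(!binMask(exp))
  # cell counts proportional to the expectation -> OE 1 everywhere unmasked
  obs <- matrix(rep(vals * 3, 2), nrow = 2, byrow = TRUE,
                dimnames = list(c("c1", "c2"), names(bins(exp))))
  oe <- computeOE(obs, exp)
  expect_equal(unname(oeValues(oe)[1, unmasked]),
               rep(1, length(unmasked)))
  expect_true(all(is.na(oeValues(oe)[, binMask(exp)])))
  # a cell whose observed fraction in bin b is twice the expected fraction
  # has OE(b) = 2, by direct construction of the fractions
  frac <- vals / sum(vals[unmasked])
  obs2 <- matrix(frac, 1, dimnames = list("c", names(bins(exp))))
  obs2[1, unmasked[1]] <- 2 * frac[unmasked[1]]
  oe2 <- computeOE(obs2 * 1000, exp)
  expect_equal(unname(oeValues(oe2)[1, unmasked[1]]),
               2 * sum(frac[unmasked]) / sum(obs2[1, unmasked]))
  # random cell: matches an independent one-line recomputation
  set.seed(3)
  obs3 <- matrix(rpois(length(vals), vals), 1,
                 dimnames = list("c", names(bins(exp))))
  oe3 <- computeOE(obs3, exp)
  manual <- (obs3[1, ] / sum(obs3[1, unmasked])) /
    (vals / sum(vals[unmasked]))
  expect_equal(unname(oeValues(oe3)[1, unmasked]), unname(manual[unmasked]))
})

test_that("OE is invariant to uniform scaling of a cell's counts", {
  g <- fixtureGenome()
  exp <- expectedDamid(g)
  set.seed(4)
  obs <- matrix(rpois(2 * length(expectedValues(exp)), 4), 2,
                dimnames = list(c("a", "b"), names(bins(exp))))
  obs[2, ] <- obs[1, ] * 7
  oe <- oeValues(computeOE(obs, exp))
  expect_equal(oe[1, ], oe[2, ])
})

test_that("zero-count cells are flagged rather than divided", {
  g <- fixtureGenome()
  exp <- expectedDamid(g)
  obs <- matrix(0, 2, length(expectedValues(exp)),
                dimnames = list(c("empty", "full"), names(bins(exp))))
  obs[2, !binMask(exp)] <- 5
  oe <- computeOE(obs, exp)
  expect_identical(oe@emptyCells, "empty")
  expect_true(all(is.na(oeValues(oe)[1, ])))
})

test_that("gene aggregation respects the strand-aware upstream flank", {
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1"),
    IRanges::IRanges(start = c(10001, 30001), end = c(20000, 40000)),
    strand = c("+", "-"))
  names(genes) <- c("gplus", "gminus")
  ev <- data.frame(
    cell = "c1", chrom = "chr1",
    # 6000: within 5 kb upstream of the + gene TSS (10001); 5000: 1 bp past
    # 44000: within the - gene's upstream flank (past its end coordinate)
    # 45001: 1 bp past that flank
    pos = c(6000L, 5000L, 44000L, 45001L),
    strand = "+", umi = "AAA", modality = "chic", allele = "none",
    weight = 1L)
  m <- aggregateGenes(ev, genes, flank = 5000)
  expect_equal(unname(m["c1", "gplus"]), 1)
  expect_equal(unname(m["c1", "gminus"]), 1)
})
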