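test_that("demultiplexing requires a zero-mismatch barcode", {
  bt <- data.table::data.table(barcode = c("ACGTACGT", "TTTTCCCC"),
                               cell = c("cellA", "cellB"))
  reads <- data.frame(
    name = c("r1", "r2"),
    sequence = c(paste0("AAA", "ACGTACGT", "TC", "GGGGAATT"),
                 paste0("AAA", "ACGTACGA", "TC", "GGGGAATT"))  # 1 mismatch
  )
  dm <- demultiplex(reads, bt)
  expect_identical(dm$cell, c("cellA", NA))
  expect_identical(dm$umi[1], "AAA")
  expect_identical(dm$insert[1], "TCGGGGAATT")
  # empty input, duplicate barcodes
  expect_identical(nrow(demultiplex(reads[0, ], bt)), 0L)
  btBad <- data.table::data.table(barcode = c("ACGTACGT", "ACGTACGT"),
                                  cell = c("a", "b"))
  expect_error(demultiplex(reads, btBad), "duplicate")
})

test_that("the toy aligner resolves unique hits, repeats and both strands", {
  g <- fixtureGenome()
  s <- chromStrings(g)[[2]]
  ins <- substring(s, 501, 530)  # unique 30-mer by construction
  al <- toyAlign(ins, g)
  expect_identical(al$status, "unique")
  expect_identical(al$chrom, "chr2")
  expect_identical(al$pos, 501L)
  expect_identical(al$strand, "+")
  expect_gte(al$mapq, 10L)
  # reverse complement maps to the same locus on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ins)))
  al2 <- toyAlign(rc, g)
  expect_identical(al2$pos, 501L)
  expect_identical(al2$strand, "-")
  # planted repeat: multi-hit, mapq below the MAPQ 10 filter
  gr <- fixtureRepeatGenome()
  rr <- gr@repeatRegions
  rep30 <- substring(chromStrings(gr)[[1]], GenomicRanges::start(rr)[1] + 5,
                     GenomicRanges::start(rr)[1] + 34)
  al3 <- toyAlign(rep30, gr)
  expect_identical(al3$status, "multi")
  expect_lt(al3$mapq, 10L)
  # too-short insert
  expect_identical(toyAlign("ACGT", g)$status, "too_short")
})

test_that("modality classification follows the GATC / A-T / TC rules", {
  g <- fixtureGenome()
  s <- chromStrings(g)[[1]]
  motif <- gatcPositions(g)$chr1[3]
  damidIns <- substring(s, motif + 2, motif + 31)        # starts TC, on motif
  # ChIC candidates: unique alignments starting with specific bases
  findStart <- function(base) {
    for (p in seq(200, nchar(s) - 40)) {
      if (substring(s, p, p) == base &&
          !(base == "T" && substring(s, p + 1, p + 1) == "C") &&
          substring(s, p - 2, p + 1) != "GATC") {
        return(p)
      }
    }
    stop("no start found")
  }
  pA <- findStart("A"); pG <- findStart("G")
  # TC-starting, not motif-anchored
  pTC <- NA
  for (p in seq(200, nchar(s) - 40)) {
    if (substring(s, p, p + 1) == "TC" && substring(s, p - 2, p + 1) != "GATC") {
      pTC <- p; break
    }
  }
  dm <- data.table::data.table(
    name = c("damid", "chicA", "tc", "g"),
    cell = "cellA", umi = "AAA",
    insert = c(damidIns, substring(s, pA, pA + 29),
               substring(s, pTC, pTC + 29), substring(s, pG, pG + 29))
  )
  cl <- classifyModality(dm, g, combinedLibrary = TRUE)
  expect_identical(cl$modality, c("damid", "chic", "discarded", "discarded"))
  expect_identical(cl$pos[1], motif)   # DamID recorded at the motif start
  expect_identical(cl$pos[2], pA)      # ChIC recorded at the cut site
  # TC exclusion only applies to combined libraries
  clSolo <- classifyModality(dm, g, combinedLibrary = FALSE)
  expect_identical(clSolo$modality[3], "chic")
})

test_that("classification recovers the hidden truth on simulated reads", {
  g <- fixtureGenome()
  bt <- makeBarcodeTable(6, seed = 2)
  rd <- simulateReads(g, 2000, bt, fracDamid = 0.5, contamRate = 0.05,
                      seed = 13)
  cl <- classifyModality(demultiplex(rd, bt), g)
  called <- cl$modality[match(rd$name, cl$name)]
  clean <- rd$clean
  expect_true(all(called[clean] == rd$trueModality[clean]))
  expect_true(all(called[!clean] == "discarded"))
  # positions and strands match the hidden truth for clean reads
  expect_identical(cl$pos[match(rd$name[clean], cl$name)],
                   rd$truePos[clean])
  expect_identical(cl$strand[match(rd$name[clean], cl$name)],
                   rd$trueStrand[clean])
})

test_that("allele assignment follows NM-then-AS with antisymmetry", {
  expect_identical(assignAllele(0, 40, 2, 40), "allele_a")
  expect_identical(assignAllele(1, 40, 1, 60), "allele_b")
  expect_identical(assignAllele(1, 50, 1, 50), "ambiguous")
  expect_identical(assignAllele(NA, NA, 1, 30), "allele_b")
  expect_identical(assignAllele(NA, NA, NA, NA), "none")
  # antisymmetry under swapping the two alignment records
  set.seed(8)
  for (i in 1:50) {
    nm <- sample(0:3, 2, replace = TRUE)
    as_ <- sample(c(30, 40, 50), 2, replace = TRUE)
    fwd <- assignAllele(nm[1], as_[1], nm[2], as_[2])
    rev <- assignAllele(nm[2], as_[2], nm[1], as_[1])
    expected <- c(allele_a = "allele_b", allele_b = "allele_a",
                  ambiguous = "ambiguous")[[fwd]]
    expect_identical(rev, expected)
  }
})

test_that("UMI deduplication is ploidy-aware, idempotent and order-invariant", {
  base <- data.frame(cell = "c1", chrom = "chr1", pos = 100L, strand = "+",
                     umi = "AAA", modality = "damid")
  three <- rbind(base, base, base)
  et1 <- dedupEvents(three, "haploid_or_allelic")
  expect_identical(nrow(events(et1)), 1L)
  expect_identical(uniqueCounts(et1)$n, 1L)
  et2 <- dedupEvents(three, "diploid")
  expect_identical(uniqueCounts(et2)$n, 2L)
  # distinct UMIs stay distinct
  two <- rbind(base, transform(base, umi = "CCC"))
  expect_identical(nrow(events(dedupEvents(two, "haploid_or_allelic"))), 2L)
  # idempotence and shuffle invariance
  set.seed(1)
  ev <- data.frame(cell = sample(c("c1", "c2"), 200, TRUE), chrom = "chr1",
                   pos = sample(1:50, 200, TRUE),
                   strand = sample(c("+", "-"), 200, TRUE),
                   umi = sample(c("AAA", "CCC", "GGG"), 200, TRUE),
                   modality = sample(c("damid", "chic"), 200, TRUE))
  d1 <- dedupEvents(ev, "haploid_or_allelic")
  d2 <- dedupEvents(events(d1), "haploid_or_allelic")
  expect_identical(events(d1), events(d2))
  dShuf <- dedupEvents(ev[sample(nrow(ev)), ], "haploid_or_allelic")
  expect_identical(events(d1), events(dShuf))
  expect_error(dedupEvents(ev, "triploid"))
})

test_that("cell filtering applies construct-specific inclusive cutoffs", {
  mkEvents <- function(cell, nDamid, nChic, allele = "none") {
    rbind(
      if (nDamid) data.frame(cell = cell, chrom = "chr1",
                             pos = seq_len(nDamid), strand = "+",
                             umi = "AAA", modality = "damid",
                             allele = allele) else NULL,
      if (nChic) data.frame(cell = cell, chrom = "chr1",
                            pos = seq_len(nChic), strand = "+",
                            umi = "AAA", modality = "chic",
                            allele = allele) else NULL)
  }
  et <- dedupEvents(rbind(mkEvents("low", 4999, 1000),
                          mkEvents("ok", 5000, 1000)), "haploid_or_allelic")
  res <- filterCells(et, construct = "dam_lmnb1")
  expect_false(res$pass[res$cell == "low"])
  expect_match(res$reason[res$cell == "low"], "damid_below_cutoff")
  expect_true(res$pass[res$cell == "ok"])
  # Dam construct cutoff is 1,000 and comparisons are inclusive
  et2 <- dedupEvents(mkEvents("c", 1000, 1000), "haploid_or_allelic")
  expect_true(filterCells(et2, construct = "dam")$pass)
  # allelic mode needs >= 200 per allele per modality
  evA <- rbind(mkEvents("c", 200, 200, "allele_a"),
               mkEvents("c", 199, 200, "allele_b"))
  evA$pos[evA$allele == "allele_b"] <- evA$pos[evA$allele == "allele_b"] + 5000L
  etA <- dedupEvents(evA, "haploid_or_allelic")
  resA <- filterCells(etA, construct = "dam", allelic = TRUE,
                      damidCutoff = 1, chicCutoff = 1)
  expect_false(resA$pass)
  expect_match(resA$reason, "allele_b")
})
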