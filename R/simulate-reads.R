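#' @include simulate-genome.R
NULL

.randSeq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}

# character-level reverse complement; much cheaper than round-tripping
# through DNAStringSet for short per-read queries
.revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Build a whitelist of cell barcodes
#'
#' Samples distinct 8-nt barcodes, one per cell, with pairwise Hamming
#' distance of at least 2 so a single-base corruption can never convert one
#' whitelisted barcode into another.
#'
#' @param nCells Number of cells.
#' @param seed Integer seed.
#' @return data.table with columns \code{barcode} (8 nt) and \code{cell}.
#' @export
makeBarcodeTable <- function(nCells, seed = 1L) {
  stopifnot(nCells >= 1L)
  set.seed(seed)
  picked <- character(0)
  while (length(picked) < nCells) {
    cand <- .randSeq(1L, 8L)
    ok <- TRUE
    for (b in picked) {
      d <- sum(strsplit(cand, "")[[1]] != strsplit(b, "")[[1]])
      if (d < 2L) { ok <- FALSE; break }
    }
    if (ok) picked <- c(picked, cand)
  }
  data.table::data.table(barcode = picked,
                         cell = sprintf("cell%03d", seq_len(nCells)))
}

# One DamID molecule: insert starts at the TC of a GATC motif (GA digested
# off). Returns NULL when the fragment would run off the chromosome.
.damidInsert <- function(genome, chr, motif, strand, readLen) {
  s <- chromStrings(genome)[[chr]]
  len <- nchar(s)
  if (strand == "+") {
    st <- motif + 2L
    en <- min(st + readLen - 1L, len)
    if (en - st + 1L < 4L) return(NULL)
    substring(s, st, en)
  } else {
    en <- motif + 3L
    st <- max(en - readLen + 1L, 1L)
    if (en - st + 1L < 4L) return(NULL)
    frag <- .revcomp(substring(s, st, en))
    # fragment reads GATC... on the minus strand; drop the GA
    substring(frag, 3L)
  }
}

# One ChIC molecule cut at 1-based position p: the first sequenced base is
# the base at the cut site on the chosen strand.
.chicInsert <- function(genome, chr, p, strand, readLen) {
  s <- chromStrings(genome)[[chr]]
  len <- nchar(s)
  if (strand == "+") {
    en <- min(p + readLen - 1L, len)
    substring(s, p, en)
  } else {
    st <- max(p - readLen + 1L, 1L)
    .revcomp(substring(s, st, p))
  }
}

#' Simulate dual-modality single-cell reads with hidden ground truth
#'
#' Emits reads with the plate-based library layout
#' \code{(3 nt UMI)(8 nt barcode)(gDNA)}: DamID inserts begin at the
#' \code{TC} of a GATC motif (the \code{GA} having been digested off), ChIC
#' inserts begin at an A or T cut site (MNase preference), and each read
#' carries hidden truth columns (cell, modality, event position, strand, UMI)
#' for oracle testing. Optionally injects PCR duplicates and off-target
#' contaminant reads (random sequence absent from the genome), which violate
#' both classification rules.
#'
#' By default ChIC cut sites are rejected when the resulting insert would be
#' indistinguishable from a DamID fragment (motif-anchored after GA prepend)
#' or would start with the excluded \code{TC} dinucleotide, so that every
#' clean read is classifiable to its true modality.
#'
#' @param genome A [GenomeModel-class].
#' @param nReads Total reads to emit (> 0).
#' @param barcodeTable From [makeBarcodeTable()]; non-empty, barcodes unique.
#' @param fracDamid Proportion of molecules that are DamID (rest ChIC).
#' @param atPreference Probability that a ChIC cut starts at A/T (default 1).
#' @param dupRate Probability that an emitted read is a PCR duplicate of an
#'   earlier molecule.
#' @param contamRate Proportion of reads that are off-target contaminants.
#' @param readLen Insert length in nt.
#' @param avoidAmbiguousChic Reject ChIC sites indistinguishable from DamID
#'   or TC-starting (default TRUE).
#' @param seed Integer seed.
#'
#' @return data.table with columns \code{name}, \code{sequence} and hidden
#'   truth columns \code{trueCell}, \code{trueModality} (\code{damid},
#'   \code{chic} or \code{contaminant}), \code{trueChrom}, \code{truePos}
#'   (motif start for DamID, cut site for ChIC), \code{trueStrand},
#'   \code{trueUmi}, \code{isDuplicate}, \code{clean}.
#' @export
simulateReads <- function(genome, nReads, barcodeTable, fracDamid = 0.5,
                          atPreference = 1.0, dupRate = 0, contamRate = 0,
                          readLen = 30L, avoidAmbiguousChic = TRUE,
                          seed = 1L) {
  if (nReads <= 0) stop("nReads must be positive")
  if (!nrow(barcodeTable)) stop("barcode table is empty")
  if (anyDuplicated(barcodeTable$barcode)) stop("duplicate barcodes")
  set.seed(seed)
  chrs <- chromNames(genome)
  seqsC <- chromStrings(genome)
  motifTab <- data.table::rbindlist(lapply(chrs, function(ch)
    data.table::data.table(chrom = ch, motif = gatcPositions(genome)[[ch]])))
  if (fracDamid > 0 && !nrow(motifTab))
    stop("genome has no GATC motifs but fracDamid > 0")

  molecules <- list()
  newMolecule <- function() {
    contam <- runif(1) < contamRate
    ci <- sample.int(nrow(barcodeTable), 1L)
    umi <- .randSeq(1L, 3L)
    if (contam) {
      # random sequence; re-draw on the (vanishingly rare) chance it occurs
      # in the genome or satisfies the ChIC start rule by alignment
      repeat {
        ins <- .randSeq(1L, readLen)
        inGenome <- any(vapply(seqsC, function(s)
          grepl(ins, s, fixed = TRUE) ||
            grepl(.revcomp(ins), s, fixed = TRUE), logical(1)))
        if (!inGenome) break
      }
      return(list(cell = barcodeTable$cell[ci], umi = umi, insert = ins,
                  modality = "contaminant", chrom = NA_character_,
                  pos = NA_integer_, strand = NA_character_, clean = FALSE))
    }
    if (runif(1) < fracDamid) {
      repeat {
        mi <- sample.int(nrow(motifTab), 1L)
        strand <- sample(c("+", "-"), 1L)
        ins <- .damidInsert(genome, motifTab$chrom[mi], motifTab$motif[mi],
                            strand, readLen)
        if (!is.null(ins)) break
      }
      list(cell = barcodeTable$cell[ci], umi = umi, insert = ins,
           modality = "damid", chrom = motifTab$chrom[mi],
           pos = motifTab$motif[mi], strand = strand, clean = TRUE)
    } else {
      repeat {
        ch <- sample(chrs, 1L)
        len <- nchar(seqsC[[ch]])
        p <- sample.int(len - readLen, 1L) + (readLen %/% 2L)
        strand <- sample(c("+", "-"), 1L)
        ins <- .chicInsert(genome, ch, p, strand, readLen)
        if (nchar(ins) < readLen) next
        first <- substring(ins, 1L, 1L)
        wantAT <- runif(1) < atPreference
        if (wantAT && !(first %in% c("A", "T"))) next
        if (avoidAmbiguousChic) {
          if (substring(ins, 1L, 2L) == "TC") next
          # would the GA-prepended insert be motif-anchored?
          if (first == "T" &&
              ((strand == "+" && p >= 3L &&
                substring(seqsC[[ch]], p - 2L, p + 1L) == "GATC") ||
               (strand == "-" && p + 2L <= len &&
                substring(seqsC[[ch]], p - 1L, p + 2L) == "GATC")))
            next
        }
        break
      }
      list(cell = barcodeTable$cell[ci], umi = umi, insert = ins,
           modality = "chic", chrom = ch, pos = p, strand = strand,
           clean = TRUE)
    }
  }

  recs <- vector("list", nReads)
  nMol <- 0L
  for (i in seq_len(nReads)) {
    if (nMol > 0L && runif(1) < dupRate) {
      recs[[i]] <- c(molecules[[sample.int(nMol, 1L)]], list(dup = TRUE))
    } else {
      m <- newMolecule()
      nMol <- nMol + 1L
      molecules[[nMol]] <- m
      recs[[i]] <- c(m, list(dup = FALSE))
    }
  }
  recs <- recs[sample.int(nReads)]
  bc <- stats::setNames(barcodeTable$barcode, barcodeTable$cell)
  out <- data.table::data.table(
    name = sprintf("read%06d", seq_len(nReads)),
    sequence = vapply(recs, function(r)
      paste0(r$umi, bc[[r$cell]], r$insert), character(1)),
    trueCell = vapply(recs, `[[`, character(1), "cell"),
    trueModality = vapply(recs, `[[`, character(1), "modality"),
    trueChrom = vapply(recs, `[[`, character(1), "chrom"),
    truePos = vapply(recs, `[[`, integer(1), "pos"),
    trueStrand = vapply(recs, `[[`, character(1), "strand"),
    trueUmi = vapply(recs, `[[`, character(1), "umi"),
    isDuplicate = vapply(recs, `[[`, logical(1), "dup"),
    clean = vapply(recs, `[[`, logical(1), "clean")
  )
  out
}
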