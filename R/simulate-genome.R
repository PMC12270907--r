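#' @include AllClasses.R
NULL

BASES <- c("A", "C", "G", "T")

# Replace the G of every non-planted GATC occurrence until the sequence is
# clean. `protect` marks positions that must not be mutated (planted motifs
# and their guard flanks). Mutations can create new motifs, hence the loop.
.scrubGATC <- function(chars, protect) {
  repeat {
    s <- paste(chars, collapse = "")
    hits <- gregexpr("GATC", s, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    hits <- hits[!(hits %in% attr(protect, "planted"))]
    if (!length(hits)) return(chars)
    for (h in hits) {
      span <- h:(h + 3L)
      free <- span[!protect[span]]
      if (!length(free)) next  # cannot happen with guard flanks
      i <- free[1L]
      chars[i] <- if (chars[i] == "C") "G" else "C"
    }
  }
}

#' Generate a toy reference genome with planted GATC motifs
#'
#' Builds a random genome in which every \code{GATC} occurrence is planted at
#' a recorded position: accidental motifs arising from random base sampling
#' are destroyed, so the recorded index is exhaustive. Planted motifs carry a
#' \code{C} guard base on each side, which provably prevents overlapping
#' motifs, and are kept at least \code{edgeMargin} bp from chromosome ends so
#' that in silico expected-vector fragments never truncate below the aligner
#' minimum. With \code{unmappableBlock = TRUE} an exact 200-bp repeat is
#' copied to two locations to exercise multi-mapping masks.
#'
#' @param nChrom Number of chromosomes.
#' @param chromLen Chromosome length in bp (all chromosomes equal); must be at
#'   least 10 x \code{binSize}.
#' @param gatcDensity Motifs per kb. Densities requiring motifs closer than
#'   10 bp are rejected (motifs would overlap their guard flanks).
#' @param binSize Default bin width in bp recorded on the genome.
#' @param seed Integer seed; identical seeds reproduce identical genomes.
#' @param unmappableBlock Plant an exact duplicated 200-bp block (default
#'   FALSE: the genome is fully mappable by construction).
#' @param edgeMargin Minimum distance of a motif from either chromosome end.
#'
#' @return A [GenomeModel-class].
#' @examples
#' g <- makeGenome(nChrom = 1, chromLen = 10000, gatcDensity = 1, seed = 7)
#' length(gatcPositions(g)$chr1)
#' @export
makeGenome <- function(nChrom = 1L, chromLen = 50000L, gatcDensity = 1,
                       binSize = 1000L, seed = 1L, unmappableBlock = FALSE,
                       edgeMargin = 100L) {
  stopifnot(nChrom >= 1L, gatcDensity >= 0)
  binSize <- as.integer(binSize)
  chromLen <- as.integer(chromLen)
  if (chromLen < 10L * binSize)
    stop("chromLen must be at least 10 x binSize")
  nMotif <- as.integer(round(gatcDensity * chromLen / 1000))
  if (nMotif > 0) {
    slotWidth <- (chromLen - 2L * edgeMargin) %/% nMotif
    if (slotWidth < 10L)
      stop("gatcDensity too high: motifs would overlap")
  }
  set.seed(seed)
  seqs <- character(nChrom)
  gatc <- vector("list", nChrom)
  names(gatc) <- paste0("chr", seq_len(nChrom))
  repGR <- GenomicRanges::GRanges()
  for (ci in seq_len(nChrom)) {
    chars <- sample(BASES, chromLen, replace = TRUE)
    protect <- logical(chromLen)
    planted <- integer(0)
    if (nMotif > 0) {
      slotStarts <- edgeMargin + (seq_len(nMotif) - 1L) * slotWidth
      # leave room for motif + trailing guard inside the slot
      planted <- slotStarts + sample.int(slotWidth - 6L, nMotif, replace = TRUE)
      for (p in planted) {
        chars[p - 1L] <- "C"                # guard
        chars[p:(p + 3L)] <- c("G", "A", "T", "C")
        chars[p + 4L] <- "C"                # guard
        protect[(p - 1L):(p + 4L)] <- TRUE
      }
    }
    attr(protect, "planted") <- planted
    chars <- .scrubGATC(chars, protect)
    if (unmappableBlock && chromLen >= 2000L) {
      # source: a 200-bp window whose planted motifs (at least one) sit well
      # inside it, so the duplicated copy carries the same motifs; the
      # duplicate motif positions are recorded too (both copies multi-map)
      # motifs deep enough inside the window that a 65-nt fragment in either
      # orientation stays within the duplicated block
      winMotifs <- function(d) {
        planted[planted >= d + 70L & planted <= d + 130L]
      }
      src <- NA_integer_
      for (d in seq(edgeMargin + 10L, chromLen %/% 2L, by = 25L)) {
        m <- winMotifs(d)
        if (length(m) >= 1L &&
            !any(protect[d:(d + 199L)] &
                 !seq(d, d + 199L) %in% as.vector(outer(m, -1:4, "+"))))
          { src <- d; break }
      }
      for (dst in seq(chromLen - edgeMargin - 300L, chromLen %/% 2L,
                      by = -25L)) {
        if (is.na(src) || dst <= src + 200L) break
        if (any(protect[dst:(dst + 199L)])) next
        dstMotifs <- dst + (winMotifs(src) - src)
        cand <- chars
        cand[dst:(dst + 199L)] <- cand[src:(src + 199L)]
        protect2 <- protect
        protect2[as.vector(outer(dstMotifs, -1:4, "+"))] <- TRUE
        attr(protect2, "planted") <- sort(c(planted, dstMotifs))
        cand <- .scrubGATC(cand, protect2)
        # junction scrubbing may touch a copy; require exact identity
        if (identical(cand[dst:(dst + 199L)], cand[src:(src + 199L)])) {
          chars <- cand
          protect <- protect2
          planted <- attr(protect2, "planted")
          repGR <- c(repGR, GenomicRanges::GRanges(
            names(gatc)[ci],
            IRanges::IRanges(start = c(src, dst), width = 200L)))
          break
        }
      }
    }
    seqs[ci] <- paste(chars, collapse = "")
    gatc[[ci]] <- as.integer(sort(planted))
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- names(gatc)
  methods::new("GenomeModel", seqs = dss, gatcPositions = gatc,
               binSize = binSize, repeatRegions = repGR)
}

#' Consecutive non-overlapping bin grid of a genome
#'
#' Tiles every chromosome with half-open bins of \code{binSize} bp; the last
#' bin of each chromosome may be shorter.
#'
#' @param genome A [GenomeModel-class].
#' @param binSize Bin width in bp; defaults to the genome's recorded size.
#' @return A [GenomicRanges::GRanges] with one range per bin, named
#'   \code{chrom:binIndex}.
#' @export
binGrid <- function(genome, binSize = genome@binSize) {
  binSize <- as.integer(binSize)
  len <- chromLengths(genome)
  chroms <- character(0); st <- integer(0); en <- integer(0); idx <- integer(0)
  for (chr in names(len)) {
    n <- ceiling(len[[chr]] / binSize)
    s <- (seq_len(n) - 1L) * binSize + 1L
    chroms <- c(chroms, rep(chr, n))
    st <- c(st, s)
    en <- c(en, pmin(s + binSize - 1L, len[[chr]]))
    idx <- c(idx, seq_len(n))
  }
  gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(start = st, end = en))
  names(gr) <- paste0(chroms, ":", idx)
  gr
}

#' Map 1-based genomic positions to global bin indices
#'
#' @param chrom Character vector of chromosome names.
#' @param pos 1-based positions.
#' @param bins A bin grid from [binGrid()].
#' @return Integer indices into \code{bins} (NA when out of range).
#' @export
binIndex <- function(chrom, pos, bins) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, bins)
  out <- rep(NA_integer_, length(q))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  out
}
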