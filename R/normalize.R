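#' @include readproc.R
NULL

#' Bin UMI-unique events into a cells x bins count matrix
#'
#' Each unique event increments exactly one bin; bins are half-open with the
#' convention that a 1-based position p falls in bin floor((p - 1)/binSize).
#' Events beyond the chromosome length are an error. Event weights (ploidy)
#' are applied.
#'
#' @param eventTable An [EventTable-class] (or a data.frame with the same
#'   columns).
#' @param genome A [GenomeModel-class].
#' @param binSize Bin width in bp; default the genome's.
#' @param modality Restrict to \code{"damid"} or \code{"chic"}; default all.
#' @param cells Optional character vector fixing the row set/order.
#' @return List with \code{counts} (base matrix, cells x bins) and
#'   \code{bins} (the [GenomicRanges::GRanges] grid).
#' @export
binEvents <- function(eventTable, genome, binSize = genome@binSize,
                      modality = NULL, cells = NULL) {
  ev <- if (methods::is(eventTable, "EventTable")) eventTable@events
        else data.table::as.data.table(eventTable)
  if (!is.null(modality)) ev <- ev[ev$modality == modality]
  if (!"weight" %in% colnames(ev)) ev$weight <- 1L
  grid <- binGrid(genome, binSize)
  if (is.null(cells)) cells <- sort(unique(ev$cell))
  m <- matrix(0, length(cells), length(grid),
              dimnames = list(cells, names(grid)))
  if (nrow(ev)) {
    len <- chromLengths(genome)
    bad <- ev$pos < 1L | ev$pos > len[ev$chrom]
    if (any(bad)) stop("event position beyond chromosome length")
    bi <- binIndex(ev$chrom, ev$pos, grid)
    ri <- match(ev$cell, cells)
    keep <- !is.na(ri)
    for (k in which(keep)) m[ri[k], bi[k]] <- m[ri[k], bi[k]] + ev$weight[k]
  }
  list(counts = m, bins = grid)
}

#' In silico DamID expected vector from GATC mappability
#'
#' For every GATC motif, emits a fragment of \code{readLen} nt in each
#' orientation (starting at the motif's TC after GA digestion), passes it
#' through the same exact-match aligner and modality classifier as real
#' reads, and bins the surviving unique events. The per-bin value is the
#' maximum number of mappable unique events; on a fully mappable genome this
#' equals 2 x the number of motifs per bin. Motifs whose fragments fall in a
#' planted repeat fail the mapping-quality filter and contribute 0. Bins with
#' zero expectation are masked.
#'
#' @param genome A [GenomeModel-class].
#' @param readLen Fragment length in nt (default 65).
#' @param binSize Bin width in bp.
#' @param mapqMin,minLen Aligner thresholds as in [classifyModality()].
#' @return An [ExpectedVector-class] (modality \code{damid}).
#' @export
expectedDamid <- function(genome, readLen = 65L, binSize = genome@binSize,
                          mapqMin = 10L, minLen = 20L) {
  grid <- binGrid(genome, binSize)
  vals <- numeric(length(grid))
  for (ch in chromNames(genome)) {
    for (motif in gatcPositions(genome)[[ch]]) {
      for (strand in c("+", "-")) {
        ins <- .damidInsert(genome, ch, motif, strand, readLen)
        if (is.null(ins) || nchar(ins) < minLen) next
        al <- toyAlign(ins, genome, prependGA = TRUE, minLen = minLen)
        if (!identical(al$status[1], "unique") || al$mapq[1] < mapqMin) next
        m <- if (al$strand[1] == "+") al$pos[1]
             else al$pos[1] + nchar(ins) + 2L - 4L
        if (!(m %in% gatcPositions(genome)[[al$chrom[1]]])) next
        bi <- binIndex(al$chrom[1], m, grid)
        vals[bi] <- vals[bi] + 1
      }
    }
  }
  methods::new("ExpectedVector", values = vals, bins = grid,
               mask = vals == 0, modality = "damid",
               source = "in_silico_gatc")
}

#' ChIC expected vector from a bulk H3 control
#'
#' Bins the UMI-unique events of an H3-targeted control library; the binned
#' unique counts serve as the ChIC expectation. Bins with zero control events
#' are masked in downstream OE computation.
#'
#' @param h3Control An [EventTable-class] of control events (non-empty).
#' @param genome A [GenomeModel-class].
#' @param binSize Bin width in bp.
#' @return An [ExpectedVector-class] (modality \code{chic}).
#' @export
expectedChic <- function(h3Control, genome, binSize = genome@binSize) {
  ev <- if (methods::is(h3Control, "EventTable")) h3Control@events
        else data.table::as.data.table(h3Control)
  if (!nrow(ev)) stop("empty H3 control")
  b <- binEvents(h3Control, genome, binSize)
  vals <- colSums(b$counts)
  methods::new("ExpectedVector", values = unname(vals), bins = b$bins,
               mask = unname(vals == 0), modality = "chic",
               source = "h3_control")
}

#' Observed-over-expected normalization
#'
#' OE(c, b) = (obs(c, b) / sum_b obs(c, .)) / (exp(b) / sum_b exp(.)):
#' depth-normalized observed fraction over expected fraction, which makes OE
#' invariant to a cell's sequencing depth. Totals run over unmasked bins.
#' Masked (zero-expected) bins carry \code{NA}; cells with zero total counts
#' are flagged and their rows are \code{NA}.
#'
#' @param obs Cells x bins count matrix (from [binEvents()]) on the same bin
#'   grid as \code{expected}.
#' @param expected An [ExpectedVector-class].
#' @param modality Tag stored on the result; default the expectation's.
#' @return An [OEMatrix-class].
#' @export
computeOE <- function(obs, expected, modality = expected@modality) {
  if (ncol(obs) != length(expected@values))
    stop("observed matrix and expected vector use different bin grids")
  mask <- expected@mask
  if (all(mask)) stop("all bins masked in expected vector")
  expFrac <- expected@values / sum(expected@values[!mask])
  tot <- rowSums(obs[, !mask, drop = FALSE])
  oe <- matrix(NA_real_, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  ok <- tot > 0
  if (any(ok)) {
    obsFrac <- obs[ok, , drop = FALSE] / tot[ok]
    oe[ok, !mask] <- sweep(obsFrac[, !mask, drop = FALSE], 2,
                           expFrac[!mask], "/")
  }
  empty <- rownames(obs)[!ok]
  if (is.null(empty)) empty <- character(0)
  methods::new("OEMatrix", oe = oe, bins = expected@bins, mask = mask,
               modality = modality, emptyCells = empty)
}

#' RPKM normalization of binned counts
#'
#' counts x 1e9 / (cell depth x bin width in bp).
#'
#' @param counts Cells x bins count matrix.
#' @param binWidths Bin widths in bp (recycled).
#' @return Matrix of RPKM values.
#' @export
rpkmNormalize <- function(counts, binWidths) {
  depth <- rowSums(counts)
  w <- rep_len(binWidths, ncol(counts))
  out <- sweep(counts, 1, pmax(depth, 1), "/")
  sweep(out, 2, w, "/") * 1e9
}

#' Aggregate events over genes with an upstream flank
#'
#' Counts events overlapping \[TSS - flank, gene end\], strand-aware: for a
#' plus-strand gene the flank extends left of the start; for a minus-strand
#' gene it extends right of the end.
#'
#' @param eventTable An [EventTable-class] or data.frame of events.
#' @param genes A [GenomicRanges::GRanges] with strand and names.
#' @param flank Upstream flank in bp (default 5000).
#' @return Cells x genes count matrix.
#' @export
aggregateGenes <- function(eventTable, genes, flank = 5000L) {
  if (is.null(names(genes)) || anyDuplicated(names(genes)))
    stop("genes must carry unique names")
  st <- as.character(GenomicRanges::strand(genes))
  if (any(!st %in% c("+", "-")))
    stop("gene annotation must be stranded")
  ev <- if (methods::is(eventTable, "EventTable")) eventTable@events
        else data.table::as.data.table(eventTable)
  if (!"weight" %in% colnames(ev)) ev$weight <- 1L
  ext <- genes
  plus <- st == "+"
  GenomicRanges::start(ext)[plus] <-
    pmax(GenomicRanges::start(genes)[plus] - flank, 1L)
  GenomicRanges::end(ext)[!plus] <- GenomicRanges::end(genes)[!plus] + flank
  cells <- sort(unique(ev$cell))
  m <- matrix(0, length(cells), length(genes),
              dimnames = list(cells, names(genes)))
  if (nrow(ev)) {
    q <- GenomicRanges::GRanges(ev$chrom, IRanges::IRanges(ev$pos, width = 1L))
    hits <- GenomicRanges::findOverlaps(q, ext)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    for (k in seq_along(qi)) {
      ri <- match(ev$cell[qi[k]], cells)
      m[ri, si[k]] <- m[ri, si[k]] + ev$weight[qi[k]]
    }
  }
  m
}
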