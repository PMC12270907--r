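#' @include normalize.R
NULL

#' Binarize an OE matrix at a log2 threshold
#'
#' A (cell, bin) entry is 1 iff log2(OE) >= threshold, i.e. OE >= 2 at the
#' default threshold of 1, chosen on the bimodal distribution of OE values.
#' Masked bins are 0 with the mask retained.
#'
#' @param oe An [OEMatrix-class], or a plain numeric matrix.
#' @param thresholdLog2 Threshold on log2(OE) (default 1).
#' @return A [BinaryOccupancy-class] over the bins.
#' @export
binarize <- function(oe, thresholdLog2 = 1.0) {
  if (methods::is(oe, "OEMatrix")) {
    vals <- oe@oe
    maskRow <- oe@mask
    ids <- names(oe@bins)
  } else {
    vals <- oe
    maskRow <- rep(FALSE, ncol(vals))
    ids <- colnames(vals)
  }
  if (is.null(ids)) ids <- as.character(seq_len(ncol(vals)))
  b <- matrix(0L, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  ok <- is.finite(vals) & vals >= 2^thresholdLog2
  b[ok] <- 1L
  maskM <- matrix(rep(maskRow, each = nrow(vals)) | !is.finite(vals),
                  nrow(vals))
  dimnames(maskM) <- dimnames(vals)
  methods::new("BinaryOccupancy", mat = b, mask = maskM, featureIds = ids)
}

#' Contact frequency per feature
#'
#' CF(b) is the fraction of single cells meeting the binarization threshold
#' for feature b; cells masked for that feature are excluded. A feature
#' masked in every cell yields \code{NA}.
#'
#' @param binary A [BinaryOccupancy-class] (or a 0/1 matrix).
#' @return Named numeric vector of CF values in \[0, 1\].
#' @export
contactFrequency <- function(binary) {
  if (methods::is(binary, "BinaryOccupancy")) {
    m <- binary@mat
    m[binary@mask] <- NA_integer_
    ids <- binary@featureIds
  } else {
    m <- binary
    ids <- colnames(binary)
  }
  if (!nrow(m)) stop("contact frequency needs at least one cell")
  cf <- colMeans(m, na.rm = TRUE)
  cf[is.nan(cf)] <- NA_real_
  stats::setNames(cf, ids)
}

.mergeFilter <- function(gr, minSize, maxGap) {
  if (!length(gr)) {
    return(methods::new("DomainSet", ranges = GenomicRanges::GRanges(),
                        minSize = minSize))
  }
  merged <- GenomicRanges::reduce(gr, min.gapwidth = maxGap + 1L)
  kept <- merged[GenomicRanges::width(merged) >= minSize]
  kept <- GenomicRanges::sort(kept)
  methods::new("DomainSet", ranges = kept, minSize = minSize)
}

#' Call LADs on a pseudobulk OE track
#'
#' Runs of bins with log2(OE) >= threshold become candidate intervals;
#' candidates separated by at most \code{maxGap} bp are combined into one;
#' merged intervals shorter than \code{minSize} bp are then excluded.
#' Merging precedes size filtering, so two short runs bridged by a small gap
#' can survive as one domain.
#'
#' @param oeTrack Numeric vector of pseudobulk OE values, one per bin
#'   (\code{NA} = masked), or a one-row [OEMatrix-class].
#' @param bins The bin grid as [GenomicRanges::GRanges] (ignored when
#'   \code{oeTrack} is an OEMatrix).
#' @param thresholdLog2 Threshold on log2(OE).
#' @param minSize Minimum retained domain width in bp (default 300 kb).
#' @param maxGap Maximum bridged gap in bp (default 100 kb).
#' @return A [DomainSet-class].
#' @export
callLadsBulk <- function(oeTrack, bins = NULL, thresholdLog2 = 1.0,
                         minSize = 3e5, maxGap = 1e5) {
  if (methods::is(oeTrack, "OEMatrix")) {
    bins <- oeTrack@bins
    oeTrack <- colMeans(oeTrack@oe, na.rm = TRUE)
  }
  if (is.null(bins) || length(bins) != length(oeTrack))
    stop("bins must match the OE track")
  hot <- is.finite(oeTrack) & oeTrack >= 2^thresholdLog2
  .mergeFilter(bins[hot], minSize, maxGap)
}

#' Pseudobulk OE from single-cell counts
#'
#' Sums counts across cells, then computes OE of the summed track against
#' the expected vector.
#'
#' @param counts Cells x bins count matrix.
#' @param expected An [ExpectedVector-class].
#' @return Numeric per-bin pseudobulk OE (\code{NA} where masked).
#' @export
pseudobulkOE <- function(counts, expected) {
  pooled <- matrix(colSums(counts), nrow = 1,
                   dimnames = list("pseudobulk", colnames(counts)))
  computeOE(pooled, expected)@oe[1, ]
}

#' Consensus domains identified by both readouts
#'
#' Keeps only domains identified by both the DamID and the ChIC pseudobulk
#' calls. Retained coordinates are the intersection of overlapping pairs
#' (conservative) or, with \code{mode = "union"}, the union of each
#' overlapping pair; the minimum-size filter is re-applied afterwards.
#'
#' @param damidLads,chicLads [DomainSet-class] objects called on matched
#'   pseudobulks.
#' @param mode \code{"intersect"} (default) or \code{"union"}.
#' @param minSize Minimum width re-applied after combination; defaults to
#'   the DamID set's.
#' @return A [DomainSet-class].
#' @export
consensusDomains <- function(damidLads, chicLads,
                             mode = c("intersect", "union"),
                             minSize = damidLads@minSize) {
  mode <- match.arg(mode)
  a <- damidLads@ranges; b <- chicLads@ranges
  if (!length(a) || !length(b)) {
    return(methods::new("DomainSet", ranges = GenomicRanges::GRanges(),
                        minSize = minSize))
  }
  if (mode == "intersect") {
    out <- GenomicRanges::intersect(a, b)
  } else {
    hits <- GenomicRanges::findOverlaps(a, b)
    if (!length(hits)) {
      return(methods::new("DomainSet", ranges = GenomicRanges::GRanges(),
                          minSize = minSize))
    }
    pu <- GenomicRanges::punion(a[S4Vectors::queryHits(hits)],
                                b[S4Vectors::subjectHits(hits)],
                                fill.gap = TRUE)
    out <- GenomicRanges::reduce(pu)
  }
  out <- out[GenomicRanges::width(out) >= minSize]
  methods::new("DomainSet", ranges = GenomicRanges::sort(out),
               minSize = minSize)
}

#' Single-cell LAD calls over consensus domains
#'
#' A domain is present in a cell iff the mean OE over its bins satisfies
#' log2(mean OE) >= threshold (mean-then-log). Domains whose bins are all
#' masked in a cell are absent and flagged in the mask.
#'
#' @param oeCells An [OEMatrix-class] at bin resolution.
#' @param domainSet A [DomainSet-class] of consensus domains.
#' @param thresholdLog2 Threshold on log2(mean OE).
#' @return A [BinaryOccupancy-class], cells x domains.
#' @export
callLadsSc <- function(oeCells, domainSet, thresholdLog2 = 1.0) {
  doms <- domainSet@ranges
  hits <- GenomicRanges::findOverlaps(oeCells@bins, doms)
  nC <- nrow(oeCells@oe)
  ids <- if (!is.null(names(doms)) && !anyDuplicated(names(doms)))
    names(doms) else sprintf("domain%03d", seq_along(doms))
  m <- matrix(0L, nC, length(doms),
              dimnames = list(rownames(oeCells@oe), ids))
  mask <- matrix(FALSE, nC, length(doms), dimnames = dimnames(m))
  for (d in seq_along(doms)) {
    bi <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == d]
    if (!length(bi)) { mask[, d] <- TRUE; next }
    sub <- oeCells@oe[, bi, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    allNA <- rowSums(is.finite(sub)) == 0L
    m[, d] <- as.integer(!allNA & is.finite(mu) & mu >= 2^thresholdLog2)
    mask[allNA, d] <- TRUE
  }
  methods::new("BinaryOccupancy", mat = m, mask = mask, featureIds = ids)
}

#' Combine binarized DamID and ChIC matrices into one state encoding
#'
#' Computes (Md + Mc) + Mc per entry: 0 = absent in both, 1 = DamID only,
#' 2 = ChIC only, 3 = present in both. The encoding is a bijection from
#' \{0, 1\}^2; [decodeState()] recovers the two matrices exactly.
#'
#' @param md,mc [BinaryOccupancy-class] objects (or 0/1 matrices) of
#'   identical shape.
#' @return Integer matrix in \{0, 1, 2, 3\}.
#' @export
combineState <- function(md, mc) {
  a <- if (methods::is(md, "BinaryOccupancy")) md@mat else md
  b <- if (methods::is(mc, "BinaryOccupancy")) mc@mat else mc
  if (!identical(dim(a), dim(b))) stop("shape mismatch between Md and Mc")
  (a + b) + b
}

#' @rdname combineState
#' @param state Combined matrix from [combineState()].
#' @return For \code{decodeState}: list of matrices \code{md} and \code{mc}.
#' @export
decodeState <- function(state) {
  list(md = matrix(as.integer(state %in% c(1L, 3L)), nrow(state),
                   dimnames = dimnames(state)),
       mc = matrix(as.integer(state %in% c(2L, 3L)), nrow(state),
                   dimnames = dimnames(state)))
}

#' Sliding-window contact frequency along a cell ordering
#'
#' Orders cells by the supplied scores and computes the CF of each feature in
#' windows of \code{window} consecutive cells advanced by \code{step}. When a
#' second modality is supplied, also returns its CF and the overlap track
#' (fraction of window cells positive in both).
#'
#' @param binary A [BinaryOccupancy-class] or 0/1 matrix (cells x features).
#' @param cellOrder Numeric scores (pseudotime/latent time), one per cell.
#' @param window Window size in cells (must not exceed the cell count).
#' @param step Step between window starts.
#' @param binary2 Optional second modality, same shape.
#' @return List with \code{starts} (first ordered-cell index per window),
#'   \code{cf} (windows x features), and when \code{binary2} is given,
#'   \code{cf2} and \code{overlap}.
#' @export
slidingCf <- function(binary, cellOrder, window = 100L, step = 1L,
                      binary2 = NULL) {
  m <- if (methods::is(binary, "BinaryOccupancy")) binary@mat else binary
  if (window > nrow(m)) stop("window exceeds the number of cells")
  if (length(cellOrder) != nrow(m)) stop("one order score per cell required")
  ord <- order(cellOrder)
  m <- m[ord, , drop = FALSE]
  starts <- seq(1L, nrow(m) - window + 1L, by = step)
  winMean <- function(x) {
    cs <- rbind(0, apply(x, 2, cumsum))
    (cs[starts + window, , drop = FALSE] - cs[starts, , drop = FALSE]) / window
  }
  out <- list(starts = starts, cf = winMean(m))
  if (!is.null(binary2)) {
    m2 <- if (methods::is(binary2, "BinaryOccupancy")) binary2@mat else binary2
    if (!identical(dim(m2), dim(m))) stop("shape mismatch")
    m2 <- m2[ord, , drop = FALSE]
    out$cf2 <- winMean(m2)
    out$overlap <- winMean(m * m2)
  }
  out
}
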