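#' @include damchic-package.R
NULL

#' GenomeModel: a toy reference genome with indexed GATC motifs
#'
#' Holds chromosome sequences together with the sorted start positions of every
#' literal \code{GATC} motif and a default bin size for the binning grid. All
#' coordinates are 1-based; exported BED intervals are converted to 0-based
#' half-open on write.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot gatcPositions Named list of sorted integer vectors, one per
#'   chromosome, giving 1-based start positions of each \code{GATC} motif.
#' @slot binSize Integer, default bin width in bp.
#' @slot repeatRegions A [GenomicRanges::GRanges] of planted exact repeats
#'   (empty when the genome is fully mappable).
#'
#' @export
setClass("GenomeModel",
  representation(
    seqs = "DNAStringSet",
    gatcPositions = "list",
    binSize = "integer",
    repeatRegions = "GRanges"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- character()
  nm <- names(object@seqs)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "chromosome names must be unique and non-empty")
  if (!identical(sort(names(object@gatcPositions)), sort(nm)))
    msg <- c(msg, "gatcPositions must be named by chromosome")
  for (chr in nm) {
    p <- object@gatcPositions[[chr]]
    if (length(p)) {
      if (is.unsorted(p, strictly = TRUE))
        msg <- c(msg, sprintf("gatcPositions[[%s]] not strictly increasing", chr))
      s <- as.character(object@seqs[[chr]])
      sub <- substring(s, p, p + 3L)
      if (!all(sub == "GATC"))
        msg <- c(msg, sprintf("recorded motif in %s does not read GATC", chr))
    }
  }
  if (length(object@binSize) != 1L || object@binSize < 1L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' SimTruth: hidden ground truth for simulated single-cell occupancy
#'
#' Container for the controlled quantities of the occupancy simulator: planted
#' domain intervals, per-feature contact probabilities, establishment anchor
#' offsets and switch times, and the per-cell true latent time.
#'
#' @slot cellIds Character vector of cell identifiers.
#' @slot features A [GenomicRanges::GRanges] of planted domains with metadata
#'   columns \code{contactProb}, \code{anchorOffset} (1-based bin index within
#'   the feature), \code{switchTime}.
#' @slot trueTime Numeric in \[0, 1\], one per cell.
#' @slot noiseSd Numeric scalar.
#'
#' @export
setClass("SimTruth",
  representation(
    cellIds = "character",
    features = "GRanges",
    trueTime = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character()
  md <- S4Vectors::mcols(object@features)
  if (!all(c("contactProb", "anchorOffset", "switchTime") %in% colnames(md)))
    msg <- c(msg, "features need contactProb, anchorOffset, switchTime metadata")
  else if (any(md$contactProb < 0 | md$contactProb > 1))
    msg <- c(msg, "contactProb must lie in [0, 1]")
  if (length(object@trueTime) != length(object@cellIds))
    msg <- c(msg, "trueTime must have one value per cell")
  if (length(object@trueTime) && any(object@trueTime < 0 | object@trueTime > 1))
    msg <- c(msg, "trueTime must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' KineticParams: rates of the two-species chromatin kinetic model
#'
#' Parameters of the model du/dt = alpha * 1\[t < tSwitch\] - beta * u,
#' ds/dt = beta * u - gamma * s with u(0) = s(0) = 0. \code{u} plays the role
#' of the present-state (ChIC-like) species and \code{s} the cumulative
#' past-state (DamID-like) species. Units of time are arbitrary; rates are
#' per unit time.
#'
#' @slot alpha Production rate (> 0).
#' @slot beta Transfer rate (> 0).
#' @slot gamma Decay rate (> 0).
#' @slot tSwitch Switch moment at which production stops (> 0).
#'
#' @export
setClass("KineticParams",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 tSwitch = "numeric")
)

setValidity("KineticParams", function(object) {
  v <- c(alpha = object@alpha, beta = object@beta, gamma = object@gamma,
         tSwitch = object@tSwitch)
  if (any(lengths(list(object@alpha, object@beta, object@gamma,
                       object@tSwitch)) != 1L))
    return("all parameters must be scalars")
  if (any(!is.finite(v)) || any(v <= 0))
    return("alpha, beta, gamma and tSwitch must be positive finite reals")
  TRUE
})

#' EventTable: UMI-unique events per cell after classification and dedup
#'
#' Wraps a \code{data.table} with one row per retained UMI-unique event and
#' columns \code{cell}, \code{chrom}, \code{pos} (1-based), \code{strand},
#' \code{umi}, \code{modality} (\code{damid}/\code{chic}), \code{allele},
#' \code{weight} (1 for haploid/allelic counting, 2 for diploid).
#'
#' @slot events A data.table of events.
#' @slot ploidy Either \code{"haploid_or_allelic"} or \code{"diploid"}.
#'
#' @export
setClass("EventTable",
  representation(events = "data.table", ploidy = "character")
)

setValidity("EventTable", function(object) {
  need <- c("cell", "chrom", "pos", "strand", "umi", "modality", "allele",
            "weight")
  if (!all(need %in% colnames(object@events)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (!object@ploidy %in% c("haploid_or_allelic", "diploid"))
    return("ploidy must be 'haploid_or_allelic' or 'diploid'")
  ev <- object@events
  if (nrow(ev)) {
    key <- paste(ev$cell, ev$modality, ev$chrom, ev$pos, ev$strand, ev$umi)
    if (anyDuplicated(key))
      return("events contain duplicated (cell, modality, chrom, pos, strand, umi)")
  }
  TRUE
})

#' ExpectedVector: expected unique events per genomic bin
#'
#' The per-bin expectation against which observed counts are normalized.
#' For DamID it is derived in silico from GATC mappability; for ChIC from a
#' bulk H3 control. Bins with zero expectation are masked: their OE ratio is
#' undefined and they carry no value downstream.
#'
#' @slot values Non-negative numeric, one per bin.
#' @slot bins A [GenomicRanges::GRanges] bin grid.
#' @slot mask Logical, TRUE where expected is zero.
#' @slot modality \code{"damid"} or \code{"chic"}.
#' @slot source \code{"in_silico_gatc"} or \code{"h3_control"}.
#'
#' @export
setClass("ExpectedVector",
  representation(values = "numeric", bins = "GRanges", mask = "logical",
                 modality = "character", source = "character")
)

setValidity("ExpectedVector", function(object) {
  msg <- character()
  if (length(object@values) != length(object@bins))
    msg <- c(msg, "one value per bin required")
  if (length(object@mask) != length(object@values))
    msg <- c(msg, "one mask entry per bin required")
  if (any(object@values < 0)) msg <- c(msg, "expected values must be >= 0")
  if (any(object@values == 0 & !object@mask))
    msg <- c(msg, "zero-expected bins must be masked")
  if (length(msg)) msg else TRUE
})

#' OEMatrix: cells x bins observed-over-expected values
#'
#' Depth-normalized observed fraction divided by expected fraction per bin.
#' Masked bins (zero expectation) hold \code{NA}. Cells with zero total counts
#' are flagged in \code{emptyCells}.
#'
#' @slot oe Numeric matrix, cells in rows, bins in columns; \code{NA} where
#'   masked.
#' @slot bins Bin grid as [GenomicRanges::GRanges].
#' @slot mask Logical per bin; TRUE = masked.
#' @slot modality Character tag.
#' @slot emptyCells Character vector of zero-count cell ids.
#'
#' @export
setClass("OEMatrix",
  representation(oe = "matrix", bins = "GRanges", mask = "logical",
                 modality = "character", emptyCells = "character")
)

setValidity("OEMatrix", function(object) {
  msg <- character()
  if (ncol(object@oe) != length(object@bins))
    msg <- c(msg, "one column per bin required")
  if (length(object@mask) != length(object@bins))
    msg <- c(msg, "one mask entry per bin required")
  vals <- object@oe[, !object@mask, drop = FALSE]
  if (any(vals[is.finite(vals)] < 0))
    msg <- c(msg, "OE values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' BinaryOccupancy: cells x features presence/absence calls
#'
#' Binary occupancy over genomic bins or called domains, with a per-entry
#' mask recording where the call was undefined (all underlying bins masked).
#'
#' @slot mat Integer matrix in \{0, 1\}, cells in rows.
#' @slot mask Logical matrix of the same shape (TRUE = undefined, value 0).
#' @slot featureIds Character feature identifiers (column names).
#'
#' @export
setClass("BinaryOccupancy",
  representation(mat = "matrix", mask = "matrix", featureIds = "character")
)

setValidity("BinaryOccupancy", function(object) {
  msg <- character()
  if (!all(object@mat %in% c(0L, 1L)))
    msg <- c(msg, "values must be 0 or 1")
  if (!identical(dim(object@mat), dim(object@mask)))
    msg <- c(msg, "mask must match the matrix shape")
  if (length(object@featureIds) != ncol(object@mat))
    msg <- c(msg, "one feature id per column required")
  if (length(msg)) msg else TRUE
})

#' DomainSet: called genomic domains (LADs, anchors)
#'
#' Sorted, non-overlapping half-open genomic intervals surviving the
#' merge-then-filter rules, with per-domain metadata.
#'
#' @slot ranges A [GenomicRanges::GRanges]; metadata may include mean OE.
#' @slot minSize Minimum retained width (bp) applied at construction.
#'
#' @export
setClass("DomainSet",
  representation(ranges = "GRanges", minSize = "numeric")
)

setValidity("DomainSet", function(object) {
  gr <- object@ranges
  if (length(gr) > 1L) {
    if (is.unsorted(order(GenomicRanges::seqnames(gr), GenomicRanges::start(gr))))
      return("domains must be sorted")
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    if (length(red) != length(gr))
      return("domains must be non-overlapping")
  }
  TRUE
})

#' KineticState: fitted kinetic model and latent-time assignment
#'
#' Per (cell, feature) paired present-state (\code{u}, ChIC OE) and past-state
#' (\code{s}, DamID OE) levels after per-feature min-max normalization, the
#' fitted per-feature model parameters, per-(cell, feature) latent times, the
#' consensus per-cell latent time (fit-quality-weighted median) and the model
#' velocity du/dt at each assignment.
#'
#' @slot u Cells x features matrix, normalized present-state levels.
#' @slot s Cells x features matrix, normalized past-state levels.
#' @slot params data.frame per feature: gamma, tSwitch, horizon, mse, excluded.
#' @slot featureTime Cells x features latent times in \[0, 1\].
#' @slot cellTime Consensus per-cell latent time in \[0, 1\].
#' @slot velocity Cells x features signed du/dt on the fitted model.
#' @slot degenerate Logical; TRUE when all cells collapsed to one time.
#'
#' @export
setClass("KineticState",
  representation(u = "matrix", s = "matrix", params = "data.frame",
                 featureTime = "matrix", cellTime = "numeric",
                 velocity = "matrix", degenerate = "logical")
)

setValidity("KineticState", function(object) {
  msg <- character()
  if (!identical(dim(object@u), dim(object@s)))
    msg <- c(msg, "u and s must have identical shapes")
  ft <- object@featureTime[is.finite(object@featureTime)]
  if (length(ft) && (min(ft) < 0 || max(ft) > 1))
    msg <- c(msg, "featureTime must lie in [0, 1]")
  ct <- object@cellTime[is.finite(object@cellTime)]
  if (length(ct) && (min(ct) < 0 || max(ct) > 1))
    msg <- c(msg, "cellTime must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
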