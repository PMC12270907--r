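#' @include AllGenerics.R
NULL

#' @rdname GenomeModel-class
#' @export
setMethod("chromNames", "GenomeModel", function(x) names(x@seqs))

#' @rdname GenomeModel-class
#' @export
setMethod("chromLengths", "GenomeModel", function(x) {
  stats::setNames(Biostrings::width(x@seqs), names(x@seqs))
})

#' @rdname GenomeModel-class
#' @export
setMethod("gatcPositions", "GenomeModel", function(x) x@gatcPositions)

#' @rdname GenomeModel-class
#' @export
setMethod("binSize", "GenomeModel", function(x) x@binSize)

#' Chromosome sequences as character strings
#'
#' @param genome A [GenomeModel-class].
#' @return Named character vector of chromosome sequences.
#' @export
chromStrings <- function(genome) {
  stats::setNames(as.character(genome@seqs), names(genome@seqs))
}

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel with", length(object@seqs), "chromosome(s)\n")
  len <- chromLengths(object)
  nm <- names(len)
  for (i in seq_along(len)) {
    cat(sprintf("  %s: %d bp, %d GATC motif(s)\n", nm[i], len[i],
                length(object@gatcPositions[[nm[i]]])))
  }
  cat("  bin size:", object@binSize, "bp;",
      length(object@repeatRegions), "planted repeat region(s)\n")
})

#' @rdname EventTable-class
#' @export
setMethod("events", "EventTable", function(x) data.table::copy(x@events))

#' @rdname EventTable-class
#' @param ... Unused.
#' @export
setMethod("uniqueCounts", "EventTable", function(x, ...) {
  ev <- x@events
  if (!nrow(ev)) {
    return(data.table::data.table(cell = character(), modality = character(),
                                  n = numeric()))
  }
  out <- ev[, list(n = sum(weight)), by = c("cell", "modality")]
  data.table::setorderv(out, c("cell", "modality"))
  out[]
})

setMethod("show", "EventTable", function(object) {
  ev <- object@events
  cat("EventTable:", nrow(ev), "UMI-unique events,",
      length(unique(ev$cell)), "cell(s), ploidy:", object@ploidy, "\n")
  if (nrow(ev)) {
    tab <- table(ev$modality)
    cat("  modalities:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' @rdname ExpectedVector-class
#' @param x An \code{ExpectedVector}.
#' @export
setMethod("expectedValues", "ExpectedVector", function(x) x@values)

#' @rdname ExpectedVector-class
#' @export
setMethod("binMask", "ExpectedVector", function(x) x@mask)

#' @rdname ExpectedVector-class
#' @export
setMethod("bins", "ExpectedVector", function(x) x@bins)

setMethod("show", "ExpectedVector", function(object) {
  cat(sprintf("ExpectedVector (%s, %s): %d bins, %d masked\n",
              object@modality, object@source, length(object@values),
              sum(object@mask)))
})

#' @rdname OEMatrix-class
#' @export
setMethod("oeValues", "OEMatrix", function(x) x@oe)

#' @rdname OEMatrix-class
#' @export
setMethod("binMask", "OEMatrix", function(x) x@mask)

#' @rdname OEMatrix-class
#' @export
setMethod("bins", "OEMatrix", function(x) x@bins)

setMethod("show", "OEMatrix", function(object) {
  cat(sprintf("OEMatrix (%s): %d cell(s) x %d bin(s), %d masked bin(s)",
              object@modality, nrow(object@oe), ncol(object@oe),
              sum(object@mask)), "\n")
  if (length(object@emptyCells))
    cat("  zero-count cells:", length(object@emptyCells), "\n")
})

#' @rdname BinaryOccupancy-class
#' @export
setMethod("occupancy", "BinaryOccupancy", function(x) x@mat)

#' @rdname BinaryOccupancy-class
#' @export
setMethod("occupancyMask", "BinaryOccupancy", function(x) x@mask)

setMethod("show", "BinaryOccupancy", function(object) {
  cat(sprintf("BinaryOccupancy: %d cell(s) x %d feature(s), fill %.3f\n",
              nrow(object@mat), ncol(object@mat), mean(object@mat)))
})

#' @rdname DomainSet-class
#' @export
setMethod("domains", "DomainSet", function(x) x@ranges)

setMethod("show", "DomainSet", function(object) {
  cat("DomainSet:", length(object@ranges), "domain(s), min size",
      object@minSize, "bp\n")
  if (length(object@ranges)) {
    cat("  total width:", sum(GenomicRanges::width(object@ranges)), "bp\n")
  }
})

#' @rdname SimTruth-class
#' @export
setMethod("trueTime", "SimTruth", function(x) {
  stats::setNames(x@trueTime, x@cellIds)
})

#' @rdname SimTruth-class
#' @export
setMethod("domains", "SimTruth", function(x) x@features)

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@cellIds), "cell(s),",
      length(object@features), "planted feature(s), noise sd",
      object@noiseSd, "\n")
})

#' @rdname KineticState-class
#' @param ... For \code{latentTime}: \code{consensus = TRUE} (default) returns
#'   the per-cell consensus; \code{consensus = FALSE} the cells x features
#'   matrix of per-feature times.
#' @export
setMethod("latentTime", "KineticState", function(x, consensus = TRUE) {
  if (consensus) x@cellTime else x@featureTime
})

setMethod("show", "KineticState", function(object) {
  cat(sprintf("KineticState: %d cell(s) x %d feature(s), %d excluded feature(s)%s\n",
              nrow(object@u), ncol(object@u), sum(object@params$excluded),
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "KineticParams", function(object) {
  cat(sprintf("KineticParams: alpha=%.3g beta=%.3g gamma=%.3g tSwitch=%.3g\n",
              object@alpha, object@beta, object@gamma, object@tSwitch))
})
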