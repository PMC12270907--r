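#' @include AllClasses.R
NULL

#' @rdname GenomeModel-class
#' @param x A \code{GenomeModel}.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeModel-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeModel-class
#' @export
setGeneric("gatcPositions", function(x) standardGeneric("gatcPositions"))

#' @rdname GenomeModel-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname EventTable-class
#' @param x An \code{EventTable}.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname EventTable-class
#' @export
setGeneric("uniqueCounts", function(x, ...) standardGeneric("uniqueCounts"))

#' @rdname OEMatrix-class
#' @param x An \code{OEMatrix} or \code{ExpectedVector}.
#' @export
setGeneric("oeValues", function(x) standardGeneric("oeValues"))

#' @rdname ExpectedVector-class
#' @export
setGeneric("expectedValues", function(x) standardGeneric("expectedValues"))

#' @rdname OEMatrix-class
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))

#' @rdname OEMatrix-class
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname DomainSet-class
#' @param x A \code{DomainSet} or \code{SimTruth}.
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname BinaryOccupancy-class
#' @param x A \code{BinaryOccupancy}.
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname BinaryOccupancy-class
#' @export
setGeneric("occupancyMask", function(x) standardGeneric("occupancyMask"))

#' @rdname KineticState-class
#' @param x A \code{KineticState}.
#' @export
setGeneric("latentTime", function(x, ...) standardGeneric("latentTime"))

#' @rdname SimTruth-class
#' @param x A \code{SimTruth}.
#' @export
setGeneric("trueTime", function(x) standardGeneric("trueTime"))
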