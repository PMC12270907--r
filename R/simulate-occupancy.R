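#' @include simulate-genome.R
NULL

#' Construct the hidden truth for an occupancy simulation
#'
#' Plants domain intervals on a genome's bin grid with per-feature contact
#' probabilities, establishment anchor offsets and switch times, and assigns
#' every cell a true latent time in \[0, 1\].
#'
#' @param genome A [GenomeModel-class].
#' @param nCells Number of cells.
#' @param nFeatures Number of planted domains.
#' @param binsPerFeature Width of each domain in bins.
#' @param contactProb Per-feature contact probability, recycled.
#' @param anchorOffset 1-based bin offset of the establishment origin within
#'   each feature, recycled; default the centre bin.
#' @param switchTime Per-feature release onset in \[0, 1\] latent time,
#'   recycled.
#' @param cellTimes Optional per-cell true times; default uniform draws.
#' @param noiseSd Observation noise recorded on the truth object.
#' @param seed Integer seed.
#' @return A [SimTruth-class].
#' @export
makeSimTruth <- function(genome, nCells, nFeatures = 5L, binsPerFeature = 10L,
                         contactProb = 0.6, anchorOffset = NULL,
                         switchTime = 0.7, cellTimes = NULL, noiseSd = 0,
                         seed = 1L) {
  set.seed(seed)
  grid <- binGrid(genome)
  nb <- length(grid)
  if (nFeatures * (binsPerFeature + 1L) > nb)
    stop("not enough bins for the requested features")
  gap <- nb %/% nFeatures
  startBin <- (seq_len(nFeatures) - 1L) * gap + 1L
  feat <- grid[startBin]
  featEnd <- grid[pmin(startBin + binsPerFeature - 1L, nb)]
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(feat),
    IRanges::IRanges(GenomicRanges::start(feat), GenomicRanges::end(featEnd)))
  if (is.null(anchorOffset))
    anchorOffset <- rep((binsPerFeature + 1L) %/% 2L, nFeatures)
  S4Vectors::mcols(gr)$contactProb <- rep_len(contactProb, nFeatures)
  S4Vectors::mcols(gr)$anchorOffset <- rep_len(as.integer(anchorOffset),
                                               nFeatures)
  S4Vectors::mcols(gr)$switchTime <- rep_len(switchTime, nFeatures)
  S4Vectors::mcols(gr)$nBins <- rep_len(as.integer(binsPerFeature), nFeatures)
  names(gr) <- sprintf("feature%02d", seq_len(nFeatures))
  if (is.null(cellTimes)) cellTimes <- runif(nCells)
  methods::new("SimTruth", cellIds = sprintf("cell%03d", seq_len(nCells)),
               features = gr, trueTime = cellTimes, noiseSd = noiseSd)
}

# Fraction of a feature occupied at latent time t: ramps 0 -> 1 over the
# establishment phase [estStart, estStart + rampWidth], holds, then ramps
# back 1 -> 0 from switchTime over the same width.
.extentAt <- function(t, switchTime, estStart = 0.05, rampWidth = 0.25) {
  up <- pmin(pmax((t - estStart) / rampWidth, 0), 1)
  down <- pmin(pmax((t - switchTime) / rampWidth, 0), 1)
  pmax(up - down, 0)
}

# Bins of a feature occupied when a fraction `extent` is established, growing
# symmetrically bin-by-bin outward from the anchor bin.
.occupiedBins <- function(nBins, anchor, extent) {
  k <- ceiling(extent * nBins)
  if (k <= 0L) return(integer(0))
  ord <- order(abs(seq_len(nBins) - anchor), seq_len(nBins))
  sort(ord[seq_len(min(k, nBins))])
}

#' Simulate paired single-cell occupancy matrices with planted structure
#'
#' Generates DamID-like and ChIC-like binary (and count) matrices over the
#' bins of each planted feature. A cell contacts a feature with the feature's
#' contact probability; when in contact, the occupied bins grow outward from
#' the anchor bin during establishment and shrink back toward it after the
#' feature's switch time, driven by the cell's true latent time. Both
#' modalities derive from the same latent contact, thinned by
#' modality-specific dropout.
#'
#' With \code{dynamics = FALSE} (the default) every contacting cell occupies
#' the full feature, so the per-bin occupancy rate is exactly Bernoulli with
#' the planted contact probability.
#'
#' @param truth A [SimTruth-class].
#' @param nCells Number of cells (defaults to the truth's cells).
#' @param dropout Named numeric \code{c(damid = , chic = )} dropout
#'   probabilities per (cell, bin).
#' @param dynamics Drive occupancy extent by the cells' true times.
#' @param meanCount Mean of the Poisson count draw for occupied bins.
#' @param seed Integer seed.
#' @return List with elements \code{damid}, \code{chic} (each a list of
#'   \code{binary} and \code{counts} matrices, cells x feature-bins),
#'   \code{featureOf} (feature id per column), \code{binOf} (within-feature
#'   bin index per column), and \code{truth}.
#' @export
simulateOccupancy <- function(truth, nCells = length(truth@cellIds),
                              dropout = c(damid = 0, chic = 0),
                              dynamics = FALSE, meanCount = 5, seed = 1L) {
  set.seed(seed)
  feats <- truth@features
  nBinsF <- S4Vectors::mcols(feats)$nBins
  ids <- truth@cellIds[seq_len(nCells)]
  tt <- truth@trueTime[seq_len(nCells)]
  cols <- sum(nBinsF)
  featureOf <- rep(names(feats), nBinsF)
  binOf <- unlist(lapply(nBinsF, seq_len))
  latent <- matrix(0L, nCells, cols, dimnames = list(ids, NULL))
  off <- c(0L, cumsum(nBinsF))
  for (f in seq_along(feats)) {
    p <- S4Vectors::mcols(feats)$contactProb[f]
    anchor <- S4Vectors::mcols(feats)$anchorOffset[f]
    sw <- S4Vectors::mcols(feats)$switchTime[f]
    contact <- rbinom(nCells, 1L, p) == 1L
    for (c in which(contact)) {
      ext <- if (dynamics) .extentAt(tt[c], sw) else 1
      ob <- .occupiedBins(nBinsF[f], anchor, ext)
      latent[c, off[f] + ob] <- 1L
    }
  }
  thin <- function(rate) {
    keep <- matrix(rbinom(length(latent), 1L, 1 - rate), nrow(latent))
    b <- latent * keep
    cnt <- matrix(0L, nrow(b), ncol(b), dimnames = dimnames(b))
    occ <- b == 1L
    cnt[occ] <- rpois(sum(occ), meanCount - 1) + 1L
    list(binary = b, counts = cnt)
  }
  dropout <- c(damid = unname(dropout["damid"]), chic = unname(dropout["chic"]))
  dropout[is.na(dropout)] <- 0
  list(damid = thin(dropout[["damid"]]), chic = thin(dropout[["chic"]]),
       featureOf = featureOf, binOf = binOf, truth = truth)
}
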