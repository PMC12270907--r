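#' @include dynamics.R
NULL

#' kNN z-scored cell-cycle phase enrichment
#'
#' For each cell, compares the phase composition of its k nearest neighbours
#' (Euclidean, on the supplied feature matrix, excluding the cell itself)
#' with n random draws of k cells sampled without replacement from the full
#' population (excluding the focal cell): z = (x - mu) / sigma per phase,
#' where x is the observed neighbourhood count. Phases with sigma = 0 are
#' flagged degenerate (z = 0). Also reports the per-cell ratio between the
#' G1 and G2 z-scores when both phases are present.
#'
#' @param features Cells x features numeric matrix used for the kNN graph,
#'   or a precomputed cells x cells distance matrix (\code{isDistance =
#'   TRUE}).
#' @param phases Character/factor phase label per cell (e.g. G1/S/G2 from
#'   Hoechst gating).
#' @param k Neighbourhood size (default 100; must be < number of cells).
#' @param nRand Number of random control draws (default 100).
#' @param seed Integer seed.
#' @param isDistance Interpret \code{features} as a distance matrix.
#' @return List with \code{z} (cells x phases matrix), \code{degenerate}
#'   (logical matrix), and \code{g1g2Ratio} (numeric per cell, NA when
#'   undefined).
#' @export
knnPhaseEnrichment <- function(features, phases, k = 100L, nRand = 100L,
                               seed = 1L, isDistance = FALSE) {
  phases <- as.character(phases)
  nC <- length(phases)
  if (k >= nC) stop("k must be smaller than the number of cells")
  D <- if (isDistance) as.matrix(features)
       else as.matrix(dist(features))
  if (!identical(dim(D), c(nC, nC)))
    stop("feature matrix must have one row per phased cell")
  set.seed(seed)
  lev <- sort(unique(phases))
  z <- matrix(NA_real_, nC, length(lev),
              dimnames = list(rownames(D), lev))
  degenerate <- matrix(FALSE, nC, length(lev), dimnames = dimnames(z))
  countPhases <- function(idx) {
    tab <- table(factor(phases[idx], levels = lev))
    as.numeric(tab)
  }
  for (c in seq_len(nC)) {
    others <- setdiff(seq_len(nC), c)
    nn <- others[order(D[c, others])][seq_len(k)]
    x <- countPhases(nn)
    nullCounts <- matrix(vapply(seq_len(nRand), function(r)
      countPhases(sample(others, k)), numeric(length(lev))),
      nrow = length(lev))
    mu <- rowMeans(nullCounts)
    sigma <- apply(nullCounts, 1, sd)
    zi <- (x - mu) / sigma
    deg <- sigma == 0
    zi[deg] <- 0
    z[c, ] <- zi
    degenerate[c, ] <- deg
  }
  g1g2 <- rep(NA_real_, nC)
  if (all(c("G1", "G2") %in% lev)) {
    denom <- z[, "G2"]
    g1g2 <- ifelse(denom != 0, z[, "G1"] / denom, NA_real_)
  }
  list(z = z, degenerate = degenerate, g1g2Ratio = g1g2)
}

#' Classify X-inactivation status from allelic chrX hPTM levels
#'
#' Threshold rule on the two per-allele X-chromosome summary levels: both
#' below \code{low} is \code{no_xci}; exactly one at or above \code{high}
#' with the other below \code{low} marks that allele inactive; every other
#' configuration is \code{undetermined}. The thresholds mirror the manually
#' set classification gates and default to values chosen on synthetic data.
#'
#' @param castLevel,s129Level Per-cell summary hPTM OE level on the CAST and
#'   129S1/Sv allele (no missing values).
#' @param low,high Classification thresholds.
#' @return data.table with \code{category} (\code{no_xci},
#'   \code{cast_inactive}, \code{s129_inactive}, \code{undetermined}) and
#'   \code{xiAllele} (\code{cast}, \code{s129} or NA).
#' @export
classifyXci <- function(castLevel, s129Level, low = 1, high = 2) {
  if (anyNA(castLevel) || anyNA(s129Level)) stop("missing allele value")
  n <- max(length(castLevel), length(s129Level))
  castLevel <- rep_len(castLevel, n); s129Level <- rep_len(s129Level, n)
  category <- rep("undetermined", n)
  category[castLevel < low & s129Level < low] <- "no_xci"
  category[castLevel >= high & s129Level < low] <- "cast_inactive"
  category[s129Level >= high & castLevel < low] <- "s129_inactive"
  xi <- rep(NA_character_, n)
  xi[category == "cast_inactive"] <- "cast"
  xi[category == "s129_inactive"] <- "s129"
  data.table::data.table(category = category, xiAllele = xi)
}

.XI_RULES <- c(h3k27me3_chic = "highest", h2ak119ub_chic = "highest",
               lmnb1_damid = "lowest", h3k27me3_damid = "highest",
               xist_rna = "highest")

#' Assign the inactive X allele from a dataset-specific signal rule
#'
#' Rule table: the Xi is the allele with the highest H3K27me3 (ChIC or
#' DamID), highest H2AK119Ub, highest Xist expression, or the lowest
#' Dam-LMNB1 signal. Exact ties are undetermined.
#'
#' @param datasetKind One of \code{h3k27me3_chic}, \code{h2ak119ub_chic},
#'   \code{lmnb1_damid}, \code{h3k27me3_damid}, \code{xist_rna}.
#' @param castSignal,s129Signal Per-cell allelic signal levels.
#' @return Character vector: \code{cast}, \code{s129} or
#'   \code{undetermined}.
#' @export
assignXi <- function(datasetKind, castSignal, s129Signal) {
  if (!datasetKind %in% names(.XI_RULES))
    stop("unknown dataset kind: ", datasetKind)
  n <- max(length(castSignal), length(s129Signal))
  a <- rep_len(castSignal, n); b <- rep_len(s129Signal, n)
  pickHigh <- .XI_RULES[[datasetKind]] == "highest"
  out <- rep("undetermined", n)
  hi <- a > b; lo <- a < b
  out[if (pickHigh) hi else lo] <- "cast"
  out[if (pickHigh) lo else hi] <- "s129"
  out
}

#' Call lamina-retaining, hPTM-depleted anchor regions on the Xi
#'
#' Bins with Dam-LMNB1 contact frequency at or above \code{tauLmnb1} and
#' Xi/Xa hPTM enrichment at or below \code{tauHptm} (the lamina-retaining,
#' Polycomb-depleted quadrant) are anchor candidates; candidates are merged
#' across gaps of at most \code{maxGap} bp and filtered to \code{minSize}
#' bp, as in bulk LAD calling. The thresholds default to values chosen on
#' synthetic data. Reports the fraction of the chromosome covered.
#'
#' @param cfLmnb1 Per-bin Dam-LMNB1 CF on the Xi.
#' @param hptmEnrichment Per-bin log Xi/Xa hPTM enrichment (same length).
#' @param bins Bin grid as [GenomicRanges::GRanges].
#' @param tauLmnb1,tauHptm Quadrant thresholds.
#' @param minSize,maxGap Merge/filter parameters in bp.
#' @return List with \code{anchors} (a [DomainSet-class]) and
#'   \code{coverage} (fraction of the binned chromosome length covered).
#' @export
callXiAnchors <- function(cfLmnb1, hptmEnrichment, bins, tauLmnb1 = 0.3,
                          tauHptm = 0, minSize = 3e5, maxGap = 1e5) {
  if (length(cfLmnb1) != length(hptmEnrichment) ||
      length(cfLmnb1) != length(bins))
    stop("track length mismatch")
  hot <- is.finite(cfLmnb1) & is.finite(hptmEnrichment) &
    cfLmnb1 >= tauLmnb1 & hptmEnrichment <= tauHptm
  ds <- .mergeFilter(bins[hot], minSize, maxGap)
  cov <- sum(GenomicRanges::width(ds@ranges)) /
    sum(GenomicRanges::width(bins))
  list(anchors = ds, coverage = cov)
}

.sigmoid <- function(t, lo, hi, t50, slope) {
  lo + (hi - lo) / (1 + exp(-(t - t50) / slope))
}

# Four-parameter sigmoid fit along a [0, 1] ordering; `direction` constrains
# the expected monotone trend.
.fitSigmoid <- function(t, y, direction) {
  incr <- direction == "increasing"
  loInit <- if (incr) min(y) else max(y)
  hiInit <- if (incr) max(y) else min(y)
  fit <- try(minpack.lm::nlsLM(
    y ~ .sigmoid(t, lo, hi, t50, slope),
    start = list(lo = loInit, hi = hiInit, t50 = stats::median(t),
                 slope = 0.1),
    lower = c(-Inf, -Inf, -0.5, 1e-3), upper = c(Inf, Inf, 1.5, 2),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- stats::coef(fit)
  # reject fits whose fitted trend contradicts the expected direction
  if ((incr && cf[["hi"]] < cf[["lo"]]) ||
      (!incr && cf[["hi"]] > cf[["lo"]])) return(NULL)
  cf
}

#' Onset ordering of two modalities along a cell ordering
#'
#' Fits each modality's per-cell Xi summary a four-parameter sigmoid over
#' the (rescaled) cell ordering and reports the half-point offset
#' Delta = t50(B) - t50(A): positive Delta means modality A's transition
#' precedes modality B's. A bootstrap over cells yields the confidence
#' interval and the sign rate.
#'
#' @param levelsA,levelsB Per-cell scalar summaries (e.g. mean OE over the
#'   Xi) of the two modalities.
#' @param cellOrder Pseudotime scores or day labels (coerced to numeric
#'   rank and rescaled to \[0, 1\]).
#' @param directionA,directionB Expected monotone direction per modality
#'   (\code{"increasing"} or \code{"decreasing"}).
#' @param nBoot Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return List with \code{delta}, \code{t50A}, \code{t50B}, \code{ci}
#'   (95 percent bootstrap percentile interval), \code{signPositiveRate}
#'   (fraction of replicates with positive Delta), \code{failed} (TRUE when
#'   either full fit failed; no sign is reported then).
#' @export
onsetOrdering <- function(levelsA, levelsB, cellOrder,
                          directionA = c("decreasing", "increasing"),
                          directionB = c("increasing", "decreasing"),
                          nBoot = 100L, seed = 1L) {
  directionA <- match.arg(directionA)
  directionB <- match.arg(directionB)
  n <- length(cellOrder)
  stopifnot(length(levelsA) == n, length(levelsB) == n)
  t <- rank(as.numeric(cellOrder), ties.method = "average")
  t <- (t - 1) / (n - 1)
  set.seed(seed)
  fa <- .fitSigmoid(t, levelsA, directionA)
  fb <- .fitSigmoid(t, levelsB, directionB)
  if (is.null(fa) || is.null(fb)) {
    return(list(delta = NA_real_, t50A = NA_real_, t50B = NA_real_,
                ci = c(NA_real_, NA_real_), signPositiveRate = NA_real_,
                failed = TRUE))
  }
  delta <- unname(fb[["t50"]] - fa[["t50"]])
  boot <- rep(NA_real_, nBoot)
  for (r in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ba <- .fitSigmoid(t[idx], levelsA[idx], directionA)
    bb <- .fitSigmoid(t[idx], levelsB[idx], directionB)
    if (!is.null(ba) && !is.null(bb))
      boot[r] <- bb[["t50"]] - ba[["t50"]]
  }
  ok <- boot[is.finite(boot)]
  list(delta = delta,
       t50A = unname(fa[["t50"]]), t50B = unname(fb[["t50"]]),
       ci = if (length(ok) >= 10) unname(quantile(ok, c(0.025, 0.975)))
            else c(NA_real_, NA_real_),
       signPositiveRate = if (length(ok)) mean(ok > 0) else NA_real_,
       failed = FALSE)
}
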