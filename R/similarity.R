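#' @include domains.R
NULL

#' Jaccard similarity of two binary vectors
#'
#' |A intersect B| / |A union B|; defined as 0 when both vectors are empty.
#'
#' @param a,b Binary vectors of equal length.
#' @return Value in \[0, 1\].
#' @export
jaccardIndex <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0L) return(0)
  sum(a & b) / un
}

# One curveball trade: pick two rows, keep their shared columns, reshuffle
# the columns unique to either row between them. Margins are conserved by
# construction.
.curveballSteps <- function(rowSets, nSteps) {
  nr <- length(rowSets)
  for (k in seq_len(nSteps)) {
    ij <- sample.int(nr, 2L)
    ri <- rowSets[[ij[1L]]]; rj <- rowSets[[ij[2L]]]
    shared <- ri[match(ri, rj, 0L) > 0L]
    ai <- ri[match(ri, rj, 0L) == 0L]
    aj <- rj[match(rj, ri, 0L) == 0L]
    pool <- c(ai, aj)
    if (length(ai) == 0L || length(aj) == 0L) next
    pool <- pool[sample.int(length(pool))]
    rowSets[[ij[1L]]] <- c(shared, pool[seq_along(ai)])
    rowSets[[ij[2L]]] <- c(shared, pool[length(ai) + seq_along(aj)])
  }
  rowSets
}

.rowSetsToMatrix <- function(rowSets, nc, dn) {
  m <- matrix(0L, length(rowSets), nc, dimnames = dn)
  for (i in seq_along(rowSets)) m[i, rowSets[[i]]] <- 1L
  m
}

#' Margin-preserving randomization of a binary matrix (curveball)
#'
#' Generates randomized matrices with exactly the row and column sums of the
#' input using curveball pair-extraction trades: repeatedly pick two rows and
#' reshuffle the columns unique to either between them. A burn-in of
#' \code{burnin} trades (default 5 x the number of rows) precedes the first
#' snapshot and separates successive snapshots. Degenerate matrices (all
#' zeros or all ones) admit a single configuration and are returned as
#' copies.
#'
#' @param m Binary matrix.
#' @param nPerm Number of randomized matrices (default 100).
#' @param seed Integer seed (deterministic output).
#' @param burnin Trades before/between snapshots.
#' @return List of \code{nPerm} integer matrices.
#' @export
permuteMargins <- function(m, nPerm = 100L, seed = 1L,
                           burnin = 5L * nrow(m)) {
  stopifnot(all(m %in% c(0, 1)))
  set.seed(seed)
  if (all(m == 0) || all(m == 1) || nrow(m) < 2L)
    return(replicate(nPerm, m, simplify = FALSE))
  rowSets <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1L))
  out <- vector("list", nPerm)
  for (p in seq_len(nPerm)) {
    rowSets <- .curveballSteps(rowSets, burnin)
    out[[p]] <- .rowSetsToMatrix(rowSets, ncol(m), dimnames(m))
  }
  out
}

#' z-scored Jaccard co-occurrence against a margin-preserving null
#'
#' For each (DamID cell, ChIC cell) pair, the observed Jaccard similarity of
#' their domain occupancy rows is compared with the Jaccards obtained after
#' randomizing the ChIC matrix \code{nPerm} times without altering row or
#' column totals: z = (x - mu) / sigma with mu and sigma the mean and s.d.
#' of the random controls. Pairs with sigma = 0 receive z = 0 and are
#' flagged degenerate.
#'
#' @param md,mc [BinaryOccupancy-class] objects (or 0/1 matrices) over the
#'   same domains.
#' @param pairing data.frame with columns \code{damidCell}, \code{chicCell}
#'   (row names of \code{md} / \code{mc}); default pairs identical row names.
#' @param nPerm Number of permutations (>= 2, default 100).
#' @param seed Integer seed.
#' @return data.table per pair: \code{damidCell}, \code{chicCell}, \code{x}
#'   (observed Jaccard), \code{mu}, \code{sigma}, \code{z},
#'   \code{degenerate}.
#' @export
zscoreJaccard <- function(md, mc, pairing = NULL, nPerm = 100L, seed = 1L) {
  if (nPerm < 2L) stop("nPerm must be at least 2")
  a <- if (methods::is(md, "BinaryOccupancy")) md@mat else md
  b <- if (methods::is(mc, "BinaryOccupancy")) mc@mat else mc
  if (ncol(a) != ncol(b)) stop("Md and Mc must cover the same domains")
  if (is.null(pairing)) {
    common <- base::intersect(rownames(a), rownames(b))
    pairing <- data.frame(damidCell = common, chicCell = common)
  }
  ia <- match(pairing$damidCell, rownames(a))
  ib <- match(pairing$chicCell, rownames(b))
  if (anyNA(ia) || anyNA(ib)) stop("pairing names cells absent from matrices")
  perms <- permuteMargins(b, nPerm = nPerm, seed = seed)
  nP <- nrow(pairing)
  x <- numeric(nP)
  nullJ <- matrix(0, nP, nPerm)
  for (p in seq_len(nP)) {
    x[p] <- jaccardIndex(a[ia[p], ], b[ib[p], ])
    for (k in seq_len(nPerm))
      nullJ[p, k] <- jaccardIndex(a[ia[p], ], perms[[k]][ib[p], ])
  }
  mu <- rowMeans(nullJ)
  sigma <- apply(nullJ, 1, sd)
  degenerate <- sigma == 0
  z <- ifelse(degenerate, 0, (x - mu) / sigma)
  data.table::data.table(damidCell = pairing$damidCell,
                         chicCell = pairing$chicCell,
                         x = x, mu = mu, sigma = sigma, z = z,
                         degenerate = degenerate)
}

#' z-scored similarity distributions for grouped cell pairings
#'
#' Computes [zscoreJaccard()] per pairing group (e.g. same cell in G2,
#' descendant cell in G1, random cell in G1) for downstream comparison of
#' their z distributions.
#'
#' @param md,mc As in [zscoreJaccard()].
#' @param groupings Named list of pairing data.frames (columns
#'   \code{damidCell}, \code{chicCell}); empty groups are an error.
#' @param nPerm,seed As in [zscoreJaccard()].
#' @return Named list of per-group z-score data.tables.
#' @export
pairwiseSimilarityGroups <- function(md, mc, groupings, nPerm = 100L,
                                     seed = 1L) {
  if (!length(groupings) || is.null(names(groupings)))
    stop("groupings must be a non-empty named list")
  lapply(groupings, function(g) {
    if (!nrow(g)) stop("empty pairing group")
    zscoreJaccard(md, mc, pairing = g, nPerm = nPerm, seed = seed)
  })
}
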