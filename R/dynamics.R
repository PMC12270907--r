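#' @include simulate-kinetics.R
NULL

#' Gaussian smoothing with reflection padding
#'
#' Convolves a vector with a Gaussian kernel of the given sigma (kernel
#' radius 4 sigma), reflecting the vector at both ends so the output has the
#' same length and no edge shrinkage.
#'
#' @param x Numeric vector.
#' @param sigma Kernel standard deviation in positions.
#' @return Smoothed vector of the same length.
#' @export
gaussianSmooth <- function(x, sigma = 5) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(r + 1L - seq_len(r), n)], x,
           x[pmax(n - seq_len(r), 1L)])
  as.numeric(stats::filter(pad, k, sides = 2))[(r + 1L):(r + n)]
}

# Segment SSE in O(1) from cumulative sums: cost of x[(a+1)..b].
.segCostFun <- function(x) {
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  function(a, b) {
    n <- b - a
    s <- cs[b + 1L] - cs[a + 1L]
    (cs2[b + 1L] - cs2[a + 1L]) - s^2 / n
  }
}

# Best single split of x[(a+1)..b]; returns the split index (last position of
# the left segment) and the cost reduction.
.bestSplit <- function(cost, a, b, minSeg) {
  cand <- seq(a + minSeg, b - minSeg)
  if (!length(cand)) return(NULL)
  tot <- cost(a, b)
  red <- vapply(cand, function(k) tot - cost(a, k) - cost(k, b), numeric(1))
  i <- which.max(red)
  list(split = cand[i], gain = red[i])
}

#' Binary segmentation change points (least-squares cost)
#'
#' Greedy binary segmentation: the first change point is the split of the
#' whole series that most reduces the within-segment sum of squared
#' deviations; each further change point is the best split of any current
#' segment. Splits whose cost reduction does not exceed \code{penalty} are
#' rejected, so a flat series yields no change points.
#'
#' @param x Numeric vector.
#' @param nBreaks Maximum number of change points.
#' @param minSeg Minimum segment length.
#' @param penalty Minimum cost reduction to accept a split; default
#'   \code{2 * sigma2 * log(length(x))} with sigma2 estimated from first
#'   differences.
#' @return Integer vector of change-point positions (last index of the
#'   segment left of the break), sorted; length 0 when none is accepted.
#' @export
binsegChangepoints <- function(x, nBreaks = 2L, minSeg = 5L,
                               penalty = NULL) {
  n <- length(x)
  if (n < 2L * minSeg) return(integer(0))
  if (is.null(penalty)) {
    sigma2 <- stats::var(diff(x)) / 2
    if (!is.finite(sigma2)) sigma2 <- 0
    penalty <- 2 * sigma2 * log(n)
  }
  cost <- .segCostFun(x)
  bounds <- c(0L, n)
  breaks <- integer(0)
  while (length(breaks) < nBreaks) {
    best <- NULL
    for (s in seq_len(length(bounds) - 1L)) {
      sp <- .bestSplit(cost, bounds[s], bounds[s + 1L], minSeg)
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) best <- sp
    }
    if (is.null(best) || best$gain <= penalty) break
    breaks <- sort(c(breaks, best$split))
    bounds <- sort(unique(c(0L, breaks, n)))
  }
  breaks
}

#' Detect establishment and release anchors along an ordered intensity vector
#'
#' Smooths the latent-time-ordered intensity with a Gaussian filter
#' (default sigma 5), locates up to two change points by binary segmentation
#' with a least-squares cost, and classifies each as establishment onset
#' (level increases across the break) or release onset (level decreases).
#' For each change point, the means over \code{nUp} cells upstream and
#' \code{nDown} cells downstream are reported, plus a symmetric variant over
#' \code{symWindow} cells on each side. A flat vector yields an explicit
#' null call.
#'
#' @param avgVector Per-ordered-cell mean intensity (from [orderAverage()]).
#' @param sigma Gaussian smoothing sd (positions).
#' @param nUp,nDown Cells averaged upstream/downstream of each change point.
#' @param symWindow Cells averaged on each side for the symmetric variant.
#' @param penalty Passed to [binsegChangepoints()].
#' @return List with \code{startChange}, \code{endChange} (ordered-cell
#'   indices, NA when absent), \code{null} (TRUE when no change point),
#'   \code{windows} (data.frame of upstream/downstream and symmetric means
#'   per change point) and \code{smoothed}.
#' @export
detectAnchors <- function(avgVector, sigma = 5, nUp = 75L, nDown = 10L,
                          symWindow = 50L, penalty = NULL) {
  n <- length(avgVector)
  if (n < 4L * sigma) stop("vector shorter than 4 x sigma")
  sm <- gaussianSmooth(avgVector, sigma)
  if (is.null(penalty)) {
    sigma2 <- stats::var(avgVector - sm)
    if (!is.finite(sigma2)) sigma2 <- 0
    penalty <- 2 * sigma2 * log(n)
  }
  bps <- binsegChangepoints(sm, nBreaks = 2L, penalty = penalty)
  out <- list(startChange = NA_integer_, endChange = NA_integer_,
              null = length(bps) == 0L, windows = NULL, smoothed = sm)
  if (!length(bps)) return(out)
  side <- max(5L, min(20L, n %/% 10L))
  direction <- vapply(bps, function(bp) {
    lo <- mean(sm[max(1L, bp - side + 1L):bp])
    hi <- mean(sm[(bp + 1L):min(n, bp + side)])
    sign(hi - lo)
  }, numeric(1))
  ups <- bps[direction > 0]; downs <- bps[direction < 0]
  if (length(ups)) out$startChange <- min(ups)
  if (length(downs)) out$endChange <- max(downs)
  win <- lapply(bps, function(bp) {
    data.frame(
      change = bp,
      upstreamMean = mean(avgVector[max(1L, bp - nUp + 1L):bp]),
      downstreamMean = mean(avgVector[(bp + 1L):min(n, bp + nDown)]),
      symUpMean = mean(avgVector[max(1L, bp - symWindow + 1L):bp]),
      symDownMean = mean(avgVector[(bp + 1L):min(n, bp + symWindow)])
    )
  })
  out$windows <- do.call(rbind, win)
  out
}

#' Average a feature's bins per ordered cell
#'
#' Sorts cells by the supplied order scores and returns, per ordered cell,
#' the mean (log-transformed, if given so) intensity over the feature's
#' bins.
#'
#' @param scMatrix Cells x bins matrix for one feature's bins.
#' @param cellOrder Numeric order scores, one per cell.
#' @return Numeric vector, one value per ordered cell.
#' @export
orderAverage <- function(scMatrix, cellOrder) {
  if (!ncol(scMatrix)) stop("feature has no bins")
  if (length(cellOrder) != nrow(scMatrix))
    stop("one order score per cell required")
  rowMeans(scMatrix, na.rm = TRUE)[order(cellOrder)]
}

#' Establishment anchor bin of a feature
#'
#' Applies [detectAnchors()] to each bin's ordered intensity; the anchor is
#' the bin with the earliest establishment onset (ties broken to the
#' leftmost bin and flagged). Also reports whether the release onset is
#' latest at the same bin (the same-location property of domain growth and
#' shrinkage).
#'
#' @param binMatrix Bins x ordered-cells intensity matrix for one feature
#'   (at least 3 bins; columns already in latent-time order).
#' @param sigma,penalty Passed to [detectAnchors()].
#' @return List with \code{anchorBin}, \code{tie} (logical),
#'   \code{sameLocation} (logical or NA), \code{onsets} (per-bin
#'   establishment onset), \code{releases} (per-bin release onset).
#' @export
anchorPosition <- function(binMatrix, sigma = 5, penalty = NULL) {
  nb <- nrow(binMatrix)
  if (nb < 3L) stop("anchor detection needs at least 3 bins")
  onsets <- rep(NA_integer_, nb)
  releases <- rep(NA_integer_, nb)
  for (b in seq_len(nb)) {
    an <- detectAnchors(binMatrix[b, ], sigma = sigma, penalty = penalty)
    onsets[b] <- an$startChange
    releases[b] <- an$endChange
  }
  if (all(is.na(onsets))) {
    return(list(anchorBin = NA_integer_, tie = NA, sameLocation = NA,
                onsets = onsets, releases = releases))
  }
  mn <- min(onsets, na.rm = TRUE)
  cand <- which(onsets == mn)
  anchor <- cand[1L]
  same <- if (all(is.na(releases))) NA else {
    mx <- max(releases, na.rm = TRUE)
    anchor %in% which(releases == mx)
  }
  list(anchorBin = anchor, tie = length(cand) > 1L, sameLocation = same,
       onsets = onsets, releases = releases)
}

# Trajectory library for a (beta, gamma, tSwitch) grid point on the unit
# horizon with alpha = 1 (the amplitude is absorbed by min-max
# normalization); u and s are rescaled to [0, 1].
.modelCurve <- function(beta, gamma, tSwitch, horizon, nT) {
  tg <- seq(0, horizon, length.out = nT)
  tr <- kineticTrajectory(tg, kineticParams(1, beta, gamma, tSwitch))
  list(t = tg / horizon, u = tr$u / max(tr$u), s = tr$s / max(tr$s),
       du = tr$du)
}

.assignNearest <- function(u, s, curve) {
  # squared distance of each cell to each trajectory point
  d <- outer(u, curve$u, "-")^2 + outer(s, curve$s, "-")^2
  idx <- max.col(-d, ties.method = "first")
  list(idx = idx, mse = mean(d[cbind(seq_along(u), idx)]),
       dist = d[cbind(seq_along(u), idx)])
}

.weightedMedian <- function(x, w) {
  ok <- is.finite(x) & is.finite(w) & w > 0
  x <- x[ok]; w <- w[ok]
  if (!length(x)) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- cumsum(w[o]) / sum(w[o])
  x[which(w >= 0.5)[1L]]
}

#' Fit the two-phase kinetic model and assign latent times
#'
#' Per feature, min-max normalizes the present-state (\code{u}, ChIC) and
#' past-state (\code{s}, DamID) levels to \[0, 1\] and fits the two-species
#' trajectory (induction, then release at the switch moment) by least
#' squares over a discretized grid of decay rate gamma and switch time (the
#' production/transfer scale is absorbed by the normalization, so alpha =
#' beta = 1). Each cell is assigned the trajectory time minimizing its
#' Euclidean distance in the (u, s) plane, on a fine time grid at the best
#' parameters. The consensus per-cell latent time is the fit-quality-weighted
#' median of the per-feature times (weights 1/mse), min-max rescaled to
#' \[0, 1\].
#'
#' @param u Cells x features present-state matrix (ChIC OE), >= 0.
#' @param s Cells x features past-state matrix (DamID OE), same shape.
#' @param betaGrid,gammaGrid,switchGrid Parameter grids; rates are per unit
#'   horizon (so a beta of 8 means the induction time constant is 1/8 of the
#'   observation window) and switch times are fractions of the unit horizon.
#' @param nTCoarse,nTFine Trajectory discretizations for the parameter search
#'   and the final assignment.
#' @param consensus \code{"weighted_median"} (default) or \code{"mean"}.
#' @param seed Integer seed (tie-breaking only; the fit is deterministic).
#' @return A [KineticState-class]. Features with zero variance in both
#'   channels are excluded and flagged in \code{params$excluded}.
#' @export
fitLatentTime <- function(u, s,
                          betaGrid = exp(seq(log(1), log(24),
                                             length.out = 5)),
                          gammaGrid = exp(seq(log(0.5), log(24),
                                              length.out = 6)),
                          switchGrid = seq(0.3, 0.7, length.out = 5),
                          nTCoarse = 60L, nTFine = 3000L,
                          consensus = c("weighted_median", "mean"),
                          seed = 1L) {
  consensus <- match.arg(consensus)
  stopifnot(identical(dim(u), dim(s)))
  set.seed(seed)
  nC <- nrow(u); nF <- ncol(u)
  horizon <- 1  # unit horizon; switchGrid and latent times are fractions
  minmax <- function(v) {
    r <- range(v, finite = TRUE)
    if (diff(r) == 0) return(rep(0, length(v)))
    (v - r[1]) / diff(r)
  }
  un <- apply(u, 2, minmax)
  sn <- apply(s, 2, minmax)
  featureTime <- matrix(NA_real_, nC, nF, dimnames = dimnames(u))
  velocity <- matrix(NA_real_, nC, nF, dimnames = dimnames(u))
  params <- data.frame(beta = rep(NA_real_, nF), gamma = NA_real_,
                       tSwitch = NA_real_, horizon = horizon, mse = NA_real_,
                       excluded = FALSE)
  rownames(params) <- colnames(u)
  grid <- expand.grid(beta = betaGrid, gamma = gammaGrid,
                      tSwitch = switchGrid * horizon)
  curves <- lapply(seq_len(nrow(grid)), function(gi)
    .modelCurve(grid$beta[gi], grid$gamma[gi], grid$tSwitch[gi], horizon,
                nTCoarse))
  params$excluded <- apply(u, 2, var) == 0 & apply(s, 2, var) == 0
  active <- which(!params$excluded)
  if (length(active)) {
    # coarse parameter search, vectorized across features: stack all
    # (cell, feature) points and group per-combo distances by feature
    uvec <- as.vector(un[, active, drop = FALSE])
    svec <- as.vector(sn[, active, drop = FALSE])
    fidx <- rep(seq_along(active), each = nC)
    bestMse <- rep(Inf, length(active))
    bestCombo <- rep(NA_integer_, length(active))
    for (gi in seq_len(nrow(grid))) {
      fit <- .assignNearest(uvec, svec, curves[[gi]])
      mseF <- as.vector(rowsum(fit$dist, fidx)) / nC
      sel <- mseF < bestMse
      bestMse[sel] <- mseF[sel]
      bestCombo[sel] <- gi
    }
    # fine time assignment at each feature's best parameters
    for (gi in unique(bestCombo)) {
      fs <- active[bestCombo == gi]
      fine <- .modelCurve(grid$beta[gi], grid$gamma[gi], grid$tSwitch[gi],
                          horizon, nTFine)
      for (f in fs) {
        fit <- .assignNearest(un[, f], sn[, f], fine)
        featureTime[, f] <- fine$t[fit$idx]
        velocity[, f] <- fine$du[fit$idx]
        params$mse[f] <- fit$mse
      }
      params$beta[fs] <- grid$beta[gi]
      params$gamma[fs] <- grid$gamma[gi]
      params$tSwitch[fs] <- grid$tSwitch[gi]
    }
  }
  wts <- 1 / (params$mse + 1e-6)
  wts[params$excluded] <- 0
  cellTime <- vapply(seq_len(nC), function(c) {
    ft <- featureTime[c, ]
    if (consensus == "mean") {
      ok <- is.finite(ft) & wts > 0
      if (!any(ok)) return(NA_real_)
      sum(ft[ok] * wts[ok]) / sum(wts[ok])
    } else {
      .weightedMedian(ft, wts)
    }
  }, numeric(1))
  degenerate <- !any(is.finite(cellTime))
  if (!degenerate) {
    rng <- range(cellTime, finite = TRUE)
    degenerate <- diff(rng) == 0
    if (!degenerate) cellTime <- (cellTime - rng[1]) / diff(rng)
  }
  if (degenerate) cellTime <- rep(0, nC)
  names(cellTime) <- rownames(u)
  methods::new("KineticState", u = un, s = sn, params = params,
               featureTime = featureTime, cellTime = cellTime,
               velocity = velocity, degenerate = degenerate)
}

#' Signed model velocity per (cell, feature)
#'
#' du/dt of the fitted two-phase model evaluated at each cell's assigned
#' latent time: positive during establishment (before the switch), negative
#' during release.
#'
#' @param state A [KineticState-class] from [fitLatentTime()].
#' @return Cells x features matrix of signed rates; \code{NA} for excluded
#'   features.
#' @export
velocityField <- function(state) {
  if (all(state@params$excluded)) stop("no fitted features")
  state@velocity
}

#' Distance decay of latent-time coupling between features
#'
#' For every pair of features on the same chromosome, computes the Pearson
#' correlation of their per-cell latent-time assignments and their genomic
#' midpoint distance, with a rolling mean of r over distance.
#'
#' @param featureTime Cells x features matrix of per-feature latent times.
#' @param featureCoords [GenomicRanges::GRanges], one range per feature
#'   (same order as columns).
#' @param rollWidth Rolling-mean window (pairs).
#' @return data.table with one row per pair: \code{featureA},
#'   \code{featureB}, \code{distance} (bp), \code{r}, \code{rollingR}
#'   (sorted by distance). Pairs involving a constant time vector are
#'   skipped.
#' @export
timeDistanceDecay <- function(featureTime, featureCoords, rollWidth = 11L) {
  nF <- ncol(featureTime)
  if (length(featureCoords) != nF)
    stop("one coordinate range per feature required")
  chr <- as.character(GenomicRanges::seqnames(featureCoords))
  mid <- (GenomicRanges::start(featureCoords) +
          GenomicRanges::end(featureCoords)) / 2
  rows <- list()
  for (i in seq_len(nF - 1L)) for (j in seq((i + 1L), nF)) {
    if (chr[i] != chr[j]) next
    ti <- featureTime[, i]; tj <- featureTime[, j]
    ok <- is.finite(ti) & is.finite(tj)
    if (sum(ok) < 3L || sd(ti[ok]) == 0 || sd(tj[ok]) == 0) next
    rows[[length(rows) + 1L]] <- data.table::data.table(
      featureA = colnames(featureTime)[i],
      featureB = colnames(featureTime)[j],
      distance = abs(mid[i] - mid[j]),
      r = cor(ti[ok], tj[ok])
    )
  }
  if (!length(rows)) {
    return(data.table::data.table(featureA = character(),
                                  featureB = character(),
                                  distance = numeric(), r = numeric(),
                                  rollingR = numeric()))
  }
  out <- data.table::rbindlist(rows)
  data.table::setorderv(out, "distance")
  w <- min(rollWidth, nrow(out))
  if (w %% 2L == 0L) w <- max(1L, w - 1L)
  out$rollingR <- zoo::rollmean(out$r, w, fill = NA)
  out[]
}
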