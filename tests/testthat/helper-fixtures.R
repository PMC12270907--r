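# Shared fixtures (memoized per test file) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixtureGenome <- function() {
  if (is.null(.fixtures$genome))
    .fixtures$genome <- makeGenome(nChrom = 2, chromLen = 20000,
                                   gatcDensity = 1, binSize = 1000, seed = 7)
  .fixtures$genome
}

fixtureRepeatGenome <- function() {
  if (is.null(.fixtures$repGenome))
    .fixtures$repGenome <- makeGenome(nChrom = 1, chromLen = 20000,
                                      gatcDensity = 1, binSize = 1000,
                                      seed = 11, unmappableBlock = TRUE)
  .fixtures$repGenome
}

# Independent string scan for GATC occurrences (1-based starts).
oracleScanGATC <- function(seq) {
  h <- gregexpr("GATC", seq, fixed = TRUE)[[1]]
  as.integer(h[h > 0])
}

# Piecewise RK4 integration of the two-species model; integrates the
# induction phase up to tSwitch, then the release phase, so the rate
# discontinuity never falls inside a step.
oracleRK4 <- function(times, alpha, beta, gamma, tSwitch) {
  fInd <- function(t, y, p) list(c(alpha - beta * y[1],
                                   beta * y[1] - gamma * y[2]))
  fRel <- function(t, y, p) list(c(-beta * y[1],
                                   beta * y[1] - gamma * y[2]))
  pre <- sort(unique(c(times[times <= tSwitch], tSwitch)))
  o1 <- deSolve::ode(c(u = 0, s = 0), c(0, pre), fInd, NULL,
                     method = "rk4", hini = 1e-4, maxsteps = 1e7)
  post <- times[times > tSwitch]
  res <- o1[match(times[times <= tSwitch], o1[, 1]), 2:3, drop = FALSE]
  if (length(post)) {
    init <- o1[nrow(o1), 2:3]
    o2 <- deSolve::ode(init, c(tSwitch, sort(post)), fRel, NULL,
                       method = "rk4", hini = 1e-4, maxsteps = 1e7)
    res <- rbind(res, o2[match(sort(post), o2[, 1]), 2:3, drop = FALSE])
  }
  res
}

# Exhaustive least-squares breakpoint oracles (raw SSE minimization over all
# admissible splits, via cumulative sums; fully vectorized).
oracleBestBreak1 <- function(x, minSeg = 5L) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  ks <- seq(minSeg, n - minSeg)
  sse <- (cs2[ks + 1] - cs[ks + 1]^2 / ks) +
    (cs2[n + 1] - cs2[ks + 1] - (cs[n + 1] - cs[ks + 1])^2 / (n - ks))
  ks[which.min(sse)]
}

oracleBestBreak2 <- function(x, minSeg = 5L) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  best <- NULL
  for (k1 in seq(minSeg, n - 2L * minSeg)) {
    k2 <- seq(k1 + minSeg, n - minSeg)
    sse <- (cs2[k1 + 1] - cs[k1 + 1]^2 / k1) +
      (cs2[k2 + 1] - cs2[k1 + 1] - (cs[k2 + 1] - cs[k1 + 1])^2 / (k2 - k1)) +
      (cs2[n + 1] - cs2[k2 + 1] - (cs[n + 1] - cs[k2 + 1])^2 / (n - k2))
    i <- which.min(sse)
    if (is.null(best) || sse[i] < best$sse)
      best <- list(sse = sse[i], breaks = c(k1, k2[i]))
  }
  best$breaks
}

# Brute-force per-bin histogram of events on a genome's bin grid.
oracleHistogram <- function(events, genome, binSize) {
  grid <- binGrid(genome, binSize)
  out <- numeric(length(grid))
  chrAll <- as.character(GenomicRanges::seqnames(grid))
  st <- GenomicRanges::start(grid); en <- GenomicRanges::end(grid)
  for (i in seq_len(nrow(events))) {
    hit <- which(chrAll == events$chrom[i] & st <= events$pos[i] &
                 en >= events$pos[i])
    w <- if ("weight" %in% colnames(events)) events$weight[i] else 1
    out[hit] <- out[hit] + w
  }
  out
}
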