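#' @include AllClasses.R
NULL

#' Construct kinetic model parameters
#'
#' @param alpha Production rate (> 0).
#' @param beta Transfer rate (> 0).
#' @param gamma Decay rate (> 0).
#' @param tSwitch Switch moment at which production stops (> 0).
#' @return A [KineticParams-class].
#' @export
kineticParams <- function(alpha = 1, beta = 1, gamma = 1, tSwitch = 4) {
  methods::new("KineticParams", alpha = alpha, beta = beta, gamma = gamma,
               tSwitch = tSwitch)
}

# s-species solution during induction, handling the beta == gamma limit
# (the (e^{-g t} - e^{-b t})/(g - b) term tends to -t e^{-b t}).
.sInduction <- function(t, alpha, beta, gamma) {
  if (abs(gamma - beta) < 1e-9) {
    alpha / gamma * (1 - exp(-gamma * t)) - alpha * t * exp(-gamma * t)
  } else {
    alpha / gamma * (1 - exp(-gamma * t)) +
      alpha / (gamma - beta) * (exp(-gamma * t) - exp(-beta * t))
  }
}

.sRelease <- function(tau, u0, s0, beta, gamma) {
  if (abs(gamma - beta) < 1e-9) {
    beta * u0 * tau * exp(-beta * tau) + s0 * exp(-gamma * tau)
  } else {
    beta * u0 / (gamma - beta) * (exp(-beta * tau) - exp(-gamma * tau)) +
      s0 * exp(-gamma * tau)
  }
}

#' Closed-form two-species kinetic trajectory
#'
#' Evaluates the noiseless solution of du/dt = alpha * 1\[t < tSwitch\] -
#' beta * u, ds/dt = beta * u - gamma * s with u(0) = s(0) = 0 at arbitrary
#' times. \code{u} is the present-state (ChIC-like) species, \code{s} the
#' past-state (DamID-like) species. The pre-switch steady state is
#' u = alpha/beta, s = alpha/gamma.
#'
#' @param t Numeric vector of times (>= 0).
#' @param params A [KineticParams-class] (or arguments via \code{...}).
#' @return data.frame with columns \code{t}, \code{u}, \code{s}, and
#'   \code{du} (the instantaneous du/dt).
#' @export
kineticTrajectory <- function(t, params) {
  stopifnot(methods::is(params, "KineticParams"))
  a <- params@alpha; b <- params@beta; g <- params@gamma; ts <- params@tSwitch
  u <- numeric(length(t)); s <- numeric(length(t))
  ind <- t <= ts
  u[ind] <- a / b * (1 - exp(-b * t[ind]))
  s[ind] <- .sInduction(t[ind], a, b, g)
  if (any(!ind)) {
    u0 <- a / b * (1 - exp(-b * ts))
    s0 <- .sInduction(ts, a, b, g)
    tau <- t[!ind] - ts
    u[!ind] <- u0 * exp(-b * tau)
    s[!ind] <- .sRelease(tau, u0, s0, b, g)
  }
  du <- ifelse(t <= ts, a - b * u, -b * u)
  data.frame(t = t, u = u, s = s, du = du)
}

#' Draw cell times from a Poisson event process
#'
#' Event times follow the Poisson law: inter-event gaps are exponential with
#' the given rate, and the cell times are the cumulative event times. The
#' default rate places the expected last event at \code{horizon}, so cells
#' cover both the induction and the release phase.
#'
#' @param nCells Number of cells.
#' @param rate Event rate per unit time; default \code{nCells / horizon}.
#' @param horizon Time horizon used for the default rate.
#' @return Sorted numeric vector of event times.
#' @export
poissonCellTimes <- function(nCells, rate = NULL, horizon = 8) {
  if (is.null(rate)) rate <- nCells / horizon
  cumsum(rexp(nCells, rate))
}

#' Simulate noisy two-species kinetic observations
#'
#' Draws cell times via a Poisson event process over a horizon of twice the
#' switch time, evaluates the closed-form trajectory per feature and adds
#' Gaussian observation noise. When \code{nFeatures > 1}, per-feature rates
#' are sampled log-normally around the supplied parameter means
#' (\code{sdlog = lognormalSd}); the switch time is shared.
#'
#' @param params A [KineticParams-class] giving the (mean) rates.
#' @param nCells Number of cells.
#' @param noiseSd Gaussian observation noise sd (on the raw signal scale).
#' @param nFeatures Number of features (columns).
#' @param lognormalSd sdlog of the per-feature rate draws.
#' @param rate Optional Poisson event rate (default \code{nCells / horizon}).
#' @param seed Integer seed.
#' @return List with matrices \code{u}, \code{s} (noisy observations, cells x
#'   features), \code{u0}, \code{s0} (noiseless), \code{trueTime} (hidden cell
#'   times, ascending), \code{params} (per-feature data.frame) and
#'   \code{horizon}.
#' @export
simulateKinetics <- function(params, nCells, noiseSd = 0, nFeatures = 1L,
                             lognormalSd = 0.3, rate = NULL, seed = 1L) {
  stopifnot(methods::is(params, "KineticParams"))
  set.seed(seed)
  horizon <- 2 * params@tSwitch
  tt <- poissonCellTimes(nCells, rate = rate, horizon = horizon)
  featPar <- data.frame(
    alpha = rlnorm(nFeatures, log(params@alpha), lognormalSd),
    beta = rlnorm(nFeatures, log(params@beta), lognormalSd),
    gamma = rlnorm(nFeatures, log(params@gamma), lognormalSd),
    tSwitch = rep(params@tSwitch, nFeatures)
  )
  if (nFeatures == 1L) featPar[1, 1:3] <- c(params@alpha, params@beta,
                                            params@gamma)
  u0 <- s0 <- matrix(0, nCells, nFeatures)
  for (f in seq_len(nFeatures)) {
    p <- kineticParams(featPar$alpha[f], featPar$beta[f], featPar$gamma[f],
                       featPar$tSwitch[f])
    tr <- kineticTrajectory(tt, p)
    u0[, f] <- tr$u
    s0[, f] <- tr$s
  }
  u <- pmax(u0 + matrix(rnorm(length(u0), 0, noiseSd), nCells), 0)
  s <- pmax(s0 + matrix(rnorm(length(s0), 0, noiseSd), nCells), 0)
  dimnames(u) <- dimnames(s) <- dimnames(u0) <- dimnames(s0) <-
    list(sprintf("cell%03d", seq_len(nCells)),
         sprintf("feature%02d", seq_len(nFeatures)))
  list(u = u, s = s, u0 = u0, s0 = s0, trueTime = tt, params = featPar,
       horizon = horizon)
}
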