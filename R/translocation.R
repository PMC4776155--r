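# One-dimensional Monte Carlo of receptor cytoplasm-to-nucleus translocation
# under mixed motion modes and a permeable nuclear envelope.

#' Configuration for the translocation Monte Carlo
#'
#' Particles live on the 1D segment [0, length] (micrometres from the
#' nuclear envelope at 0 to the cell membrane at `length`) and start
#' uniformly distributed. At every time step each particle independently
#' chooses one of three modes: diffusion (Gaussian step, sd sqrt(2 D dt)),
#' standing still, or direct transport toward the nucleus (step magnitude
#' Normal(v dt, v dt / 2), negative draws clamped to zero -- transport is
#' unidirectional). The membrane reflects; at the envelope (x <= 0) the
#' particle is absorbed with probability p(t) = min(1, p0 + slope t)
#' (one-way sink), otherwise reflected back to |x|.
#'
#' The default mode probabilities, D and dynein velocity are placeholders for
#' exploratory use, not measured constants; set them per scenario.
#'
#' @param length envelope-to-membrane distance, um (default 50).
#' @param nParticles number of simulated receptors (default 500).
#' @param dt time step, seconds (default 1).
#' @param tMax simulated time, seconds (default 1800).
#' @param modeProbs probabilities c(diffusion, still, transport), summing
#'   to 1.
#' @param D diffusion coefficient, um^2/s (default 9.2, a typical measured
#'   receptor mobility).
#' @param dyneinVelocity transport speed, um/s (default 1).
#' @param permeability baseline nuclear permeability p0 in [0, 1].
#' @param permeabilitySlope linear increase k of p(t) = min(1, p0 + k t),
#'   per second (default 0: constant permeability).
#' @param seed RNG seed (NA = do not seed).
#' @return A validated configuration list (class "translocationConfig").
#' @export
translocationConfig <- function(length = 50, nParticles = 500L, dt = 1,
                                tMax = 1800,
                                modeProbs = c(diffusion = 0.5, still = 0.4,
                                              transport = 0.1),
                                D = 9.2, dyneinVelocity = 1,
                                permeability = 0.1, permeabilitySlope = 0,
                                seed = NA_integer_) {
  modeProbs <- as.numeric(modeProbs)
  if (base::length(modeProbs) != 3L || any(modeProbs < 0) ||
      abs(sum(modeProbs) - 1) > 1e-9) {
    stop("modeProbs must be 3 non-negative probabilities summing to 1")
  }
  if (length <= 0 || dt <= 0 || tMax < dt) stop("invalid geometry/time settings")
  if (D < 0 || dyneinVelocity < 0) stop("rates must be non-negative")
  if (permeability < 0 || permeability > 1 || permeabilitySlope < 0) {
    stop("permeability must lie in [0, 1] with non-negative slope")
  }
  structure(list(
    length = length, nParticles = as.integer(nParticles), dt = dt, tMax = tMax,
    modeProbs = modeProbs, D = D, dyneinVelocity = dyneinVelocity,
    permeability = permeability, permeabilitySlope = permeabilitySlope,
    seed = seed
  ), class = "translocationConfig")
}

permeabilityAt <- function(config, t) {
  pmin(1, config$permeability + config$permeabilitySlope * t)
}

#' Advance particles one Monte Carlo step
#'
#' Vectorized single step of the translocation walk. Random numbers are drawn
#' for every particle slot (including already-absorbed ones) so that runs
#' with different permeabilities but a common seed are coupled by common
#' random numbers; this makes nuclear uptake monotone in permeability.
#'
#' @param x numeric vector of positions in [0, length]; NA = already absorbed.
#' @param t current time, seconds (sets the permeability).
#' @param config a [translocationConfig()].
#' @return Updated position vector; newly absorbed particles become NA.
#' @export
stepParticles <- function(x, t, config) {
  n <- length(x)
  u <- stats::runif(n)
  z <- stats::rnorm(n)
  uAbs <- stats::runif(n)
  alive <- !is.na(x)
  p <- config$modeProbs
  mode <- 1L + (u >= p[1]) + (u >= p[1] + p[2])  # 1 diff, 2 still, 3 transport
  step <- numeric(n)
  step[mode == 1L] <- z[mode == 1L] * sqrt(2 * config$D * config$dt)
  vdt <- config$dyneinVelocity * config$dt
  # transport: toward the nucleus, magnitude clamped at zero (unidirectional)
  step[mode == 3L] <- -pmax(vdt + z[mode == 3L] * vdt / 2, 0)
  xn <- x + ifelse(alive, step, 0)
  # reflect at the membrane
  over <- alive & xn > config$length
  xn[over] <- 2 * config$length - xn[over]
  xn[alive] <- pmin(xn[alive], config$length)  # guard huge steps
  # envelope: absorb with probability p(t), else reflect
  atEnv <- alive & xn <= 0
  pt <- permeabilityAt(config, t)
  absorbed <- atEnv & uAbs < pt
  xn[absorbed] <- NA_real_
  refl <- atEnv & !absorbed
  xn[refl] <- pmin(abs(xn[refl]), config$length)
  xn
}

#' Run the translocation Monte Carlo
#'
#' Initializes `nParticles` uniformly on [0, length] and advances them for
#' tMax/dt steps, recording positions, the cumulative nuclear count and the
#' cytoplasmic fraction at every step.
#'
#' @param config a [translocationConfig()].
#' @return A [TranslocationResult-class].
#' @export
runTranslocation <- function(config) {
  if (!is.na(config$seed)) set.seed(config$seed)
  n <- config$nParticles
  nSteps <- as.integer(round(config$tMax / config$dt))
  x <- stats::runif(n, 0, config$length)
  pos <- matrix(NA_real_, nSteps + 1L, n)
  pos[1, ] <- x
  nuc <- integer(nSteps + 1L)
  for (k in seq_len(nSteps)) {
    x <- stepParticles(x, (k - 1L) * config$dt, config)
    pos[k + 1L, ] <- x
    nuc[k + 1L] <- sum(is.na(x))
  }
  new("TranslocationResult",
      positions = pos, times = (0:nSteps) * config$dt,
      nuclearCount = nuc, cytoFraction = 1 - nuc / n,
      config = unclass(config))
}

#' Binned kymograph of the cytoplasmic distribution
#'
#' Histogram of surviving cytoplasmic positions per time step: the simulated
#' counterpart of an intensity kymograph from the nuclear envelope to the
#' cell membrane.
#'
#' @param result a [TranslocationResult-class].
#' @param nBins number of position bins over [0, length].
#' @return A matrix (nBins x time steps) of counts; row names give the bin
#'   centres in micrometres.
#' @export
translocationKymograph <- function(result, nBins = 50L) {
  L <- result@config$length
  edges <- seq(0, L, length.out = nBins + 1L)
  out <- apply(result@positions, 1, function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) return(integer(nBins))
    tabulate(pmin(findInterval(p, edges, rightmost.closed = TRUE), nBins),
             nbins = nBins)
  })
  rownames(out) <- sprintf("%.2f", (edges[-1] + edges[-(nBins + 1)]) / 2)
  out
}

#' Early/late depletion slope ratio (temporal concavity)
#'
#' Quantifies the shape of a cytoplasmic-fraction decay: the ratio of the
#' mean slope over the first quartile of the depletion interval to the mean
#' slope over its last quartile. Values > 1 indicate early-rapid (convex,
#' exponential-like) depletion, as produced by constant nuclear
#' permeability; values < 1 indicate delayed (sigmoidal) depletion, the
#' signature of permeability increasing with time.
#'
#' The depletion interval runs from t = 0 to the first time the series comes
#' within 5% (of its total drop) of its final value, so equilibrated tails do
#' not dilute the late slope.
#'
#' @param cytoFraction numeric decay series (or a
#'   [TranslocationResult-class]).
#' @param times optional time axis (defaults to the sample index).
#' @return The slope ratio (early / late, both slopes taken as magnitudes).
#' @export
concavityMetric <- function(cytoFraction, times = NULL) {
  if (is(cytoFraction, "TranslocationResult")) {
    times <- cytoFraction@times
    cytoFraction <- cytoFraction@cytoFraction
  }
  f <- as.numeric(cytoFraction)
  if (length(f) < 10L) stop("series too short (need >= 10 points)")
  if (is.null(times)) times <- seq_along(f) - 1
  drop <- f[1] - min(f)
  if (drop < 0.2 * abs(f[1])) stop("insufficient depletion (< 20%)")
  fEnd <- min(f)
  iEnd <- which(f <= fEnd + 0.05 * drop)[1]
  if (iEnd < 10L) iEnd <- min(length(f), 10L)
  tt <- times[1:iEnd]; ff <- f[1:iEnd]
  q <- tt[1] + (tt[iEnd] - tt[1]) * c(0.25, 0.75)
  i1 <- which(tt <= q[1])
  i2 <- which(tt >= q[2])
  slope <- function(i) (ff[max(i)] - ff[min(i)]) / (tt[max(i)] - tt[min(i)])
  s1 <- slope(i1); s2 <- slope(i2)
  if (s2 == 0) return(Inf)
  abs(s1) / abs(s2)
}
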