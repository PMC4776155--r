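# Multimodal image correlation spectroscopy: spatiotemporal correlation over
# frame lags, two-component Gaussian mixture fitting with likelihood-ratio
# model selection, and windowed kinetic maps.

#' Spatiotemporal correlation of intensity fluctuations at frame lags
#'
#' For each lag \eqn{\Delta t} the correlation surface is the average over
#' all T - \eqn{\Delta t} ordered frame pairs (t, t + \eqn{\Delta t}) of the
#' spatial cross-correlation of the fluctuation images, each pair normalized
#' by the product of the two frames' raw window mean intensities
#' (Hebert-style normalization):
#' \deqn{C(\xi,\psi,\Delta t) = \Big\langle \frac{\langle \delta I(x,y,t)\,
#'   \delta I(x{+}\xi, y{+}\psi, t{+}\Delta t)\rangle_{x,y}}
#'   {\bar I(t)\,\bar I(t{+}\Delta t)} \Big\rangle_t}
#' Spatial averaging is non-periodic with per-shift pair-count normalization.
#'
#' @param fluct a [FluctuationStack-class] (bleach-corrected, time-average
#'   removed; see [bleachCorrect()], [removeTimeAverage()]).
#' @param window a single window (one row of [tileWindows()] output, a list
#'   with row/col/size, or NULL for the full frame).
#' @param lags integer vector of frame lags (each >= 1 and < nFrames).
#' @param maxShift maximum |xi|, |psi| retained (< window size / 2).
#' @return A [CorrelationMap-class] if one lag is requested, otherwise a
#'   list of them named by lag.
#' @export
sticsCorrelate <- function(fluct, window = NULL, lags = 1L, maxShift = 8L) {
  lags <- as.integer(lags)
  deltas <- fluct@deltas
  avg <- fluct@meanImage
  if (!is.null(window)) {
    if (is.data.frame(window)) window <- as.list(window[1, ])
    deltas <- windowSlab(deltas, window)
    avg <- avg[window$row:(window$row + window$size - 1L),
               window$col:(window$col + window$size - 1L), drop = FALSE]
  }
  T <- dim(deltas)[1]; h <- dim(deltas)[2]; w <- dim(deltas)[3]
  maxShift <- as.integer(maxShift)
  if (any(lags < 1L)) stop("lags must be >= 1")
  if (any(lags >= T)) stop("lag must be smaller than the number of frames")
  if (2L * maxShift >= min(h, w)) stop("maxShift must be < window size / 2")
  # raw window means: fluctuations plus the removed time average
  mAvg <- mean(avg)
  m <- apply(deltas, 1, mean) + mAvg
  if (any(m <= 0)) stop("non-positive raw window mean; cannot normalize")
  ph <- nextPow2(h + maxShift)
  pw <- nextPow2(w + maxShift)
  # FFT of every fluctuation frame once; cross-spectra accumulate per lag
  Fmat <- matrix(0 + 0i, ph * pw, T)
  pad <- matrix(0, ph, pw)
  for (t in seq_len(T)) {
    pad[1:h, 1:w] <- deltas[t, , ]
    Fmat[, t] <- stats::fft(pad)
  }
  cnt <- pairCounts(h, w, maxShift, maxShift)
  out <- vector("list", length(lags))
  names(out) <- as.character(lags)
  for (k in seq_along(lags)) {
    lag <- lags[k]
    idx <- seq_len(T - lag)
    wpair <- 1 / (m[idx] * m[idx + lag])
    Sacc <- (Conj(Fmat[, idx, drop = FALSE]) *
               Fmat[, idx + lag, drop = FALSE]) %*% wpair
    cc <- Re(stats::fft(matrix(Sacc, ph, pw), inverse = TRUE)) / (ph * pw)
    surf <- wrapIndex(cc, maxShift, maxShift) / (cnt * (T - lag))
    out[[k]] <- new("CorrelationMap", surface = surf,
                    lagFrames = lag,
                    lagSeconds = lag * fluct@meta@frameInterval,
                    nPairs = T - lag, meta = fluct@meta)
  }
  if (length(lags) == 1L) out[[1]] else out
}

# --- Gaussian mixture model -------------------------------------------------

# par layouts: iso = (a1, sigma, eps); full = iso + (a2, mux, muy, sM, sm, th)
mixtureEval <- function(par, XI, PSI) {
  a1 <- par[1]; s1 <- par[2]; eps <- par[3]
  v <- a1 * exp(-(XI^2 + PSI^2) / (2 * s1^2)) + eps
  if (length(par) > 3) {
    a2 <- par[4]; mx <- par[5]; my <- par[6]
    sM <- par[7]; sm <- par[8]; th <- par[9]
    u <- cos(th) * (XI - mx) + sin(th) * (PSI - my)
    q <- -sin(th) * (XI - mx) + cos(th) * (PSI - my)
    v <- v + a2 * exp(-0.5 * (u^2 / sM^2 + q^2 / sm^2))
  }
  v
}

lmFit <- function(y, XI, PSI, par0, lower, upper) {
  residFn <- function(p) y - mixtureEval(p, XI, PSI)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = residFn, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(par = fit$par, sse = sum(fit$fvec^2), converged = fit$info %in% 1:4,
       residFn = residFn)
}

#' One-sided likelihood-ratio test for the anisotropic term
#'
#' Gaussian-residual likelihood-ratio statistic for nested least-squares
#' fits: \eqn{\Lambda = n \ln(SSE_{iso}/SSE_{full})}, referred to the upper
#' tail of a chi-squared distribution with `dfExtra` degrees of freedom (the
#' six extra anisotropic parameters: amplitude, two centre coordinates, two
#' sigmas, orientation). The anisotropic component is included when
#' p < 0.05.
#'
#' @param sseIso,sseFull residual sums of squares of the isotropic-only and
#'   full fits (the full fit is seeded from the isotropic optimum, so
#'   sseFull <= sseIso; if numerics violate this, p = 1 is returned and the
#'   isotropic model retained).
#' @param nPoints number of surface points fitted.
#' @param dfExtra extra parameters of the full model (default 6).
#' @return The one-sided p-value.
#' @examples
#' selectModel(1.5, 1.0, 289)  # Lambda = 289 * log(1.5) ~ 117, p << 0.05
#' @export
selectModel <- function(sseIso, sseFull, nPoints, dfExtra = 6L) {
  if (nPoints <= dfExtra + 3L) stop("too few points for the full model")
  if (!is.finite(sseIso) || !is.finite(sseFull) || sseFull > sseIso ||
      sseFull <= 0) {
    return(1)
  }
  lambda <- nPoints * log(sseIso / sseFull)
  stats::pchisq(lambda, df = dfExtra, lower.tail = FALSE)
}

# Effective number of independent surface points. Correlation surfaces are
# smooth over the PSF width, so their residuals are spatially correlated and
# the raw point count overstates the evidence available to the likelihood
# ratio. The integral of the residual autocorrelation estimates how many
# points one independent observation spans (Bretherton-style effective
# sample size); for white residuals the factor is ~1 and the raw count is
# recovered.
effectivePoints <- function(R) {
  n <- length(R)
  R <- R - mean(R)
  v <- sum(R^2)
  if (v <= 0) return(n)
  K <- 4L
  a <- xcorrNumerator(R, R, min(K, nrow(R) - 1L), min(K, ncol(R) - 1L))
  s <- max(1, sum(a / v))
  max(1, n / s)
}

# moment-based isotropic seed
isoSeed <- function(S, XI, PSI) {
  eps0 <- stats::median(S)
  w <- pmax(S - eps0, 0)
  sw <- sum(w)
  s0 <- if (sw > 0) sqrt(sum(w * (XI^2 + PSI^2)) / (2 * sw)) else 1
  c(a1 = max(S[XI == 0 & PSI == 0] - eps0, 1e-6),
    sigma = min(max(s0, 0.5), max(abs(XI))), eps = eps0)
}

# principal-axis seed for the anisotropic term from the isotropic residual
anisoSeed <- function(R, XI, PSI, maxShift) {
  w <- pmax(R, 0)
  sw <- sum(w)
  if (sw <= 0) {
    return(c(a2 = 1e-5, mux = 0, muy = 0, sM = 1.5, sm = 1, th = 0))
  }
  mx <- sum(w * XI) / sw; my <- sum(w * PSI) / sw
  cxx <- sum(w * (XI - mx)^2) / sw
  cyy <- sum(w * (PSI - my)^2) / sw
  cxy <- sum(w * (XI - mx) * (PSI - my)) / sw
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  sM <- sqrt(max(ev$values[1], 0.25))
  sm <- sqrt(max(ev$values[2], 0.2))
  th <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi
  c(a2 = max(max(R), 1e-5),
    mux = min(max(mx, -maxShift), maxShift),
    muy = min(max(my, -maxShift), maxShift),
    sM = sM, sm = max(sm, 0.2), th = th)
}

#' Fit the two-component Gaussian mixture to a correlation surface
#'
#' Least-squares fit of
#' \deqn{C(\xi,\psi) = a_1 e^{-(\xi^2+\psi^2)/(2\sigma_{iso}^2)}
#'   + a_2 e^{-\frac12 (r-\mu)^\top \Sigma^{-1} (r-\mu)} + \epsilon}
#' where the isotropic term is a centred circular Gaussian, the anisotropic
#' term an offset rotated Gaussian (sigmaMajor, sigmaMinor, theta), and
#' \eqn{\epsilon} a spatially uniform noise level (unconstrained in sign).
#' The isotropic-only model is fitted first (moment-based initialization);
#' the full model is seeded from the isotropic optimum plus a principal-axis
#' decomposition of the positive residual. Model selection is by
#' [selectModel()]; classification then applies, in order, the R-squared
#' gate (<= `r2Gate` is "noise", assessed on the selected model), and the
#' amplitude gate (a component is reported only when its amplitude exceeds
#' `ampGate`).
#'
#' @param corr a [CorrelationMap-class] (or a bare shift-labelled matrix).
#' @param lrtAlpha inclusion threshold for the anisotropic term (0.05).
#' @param r2Gate noise gate on the coefficient of determination (0.1).
#' @param ampGate minimum reportable component amplitude (1e-4).
#' @param dfExtra chi-squared degrees of freedom charged to the anisotropic
#'   term. The full model adds 6 parameters, but its centre, shape and
#'   orientation are unidentified when the amplitude is zero, so under the
#'   null each costs roughly two chi-squared degrees of freedom; the default
#'   12 was calibrated on simulated isotropic surfaces so that the nominal
#'   0.05 gate accepts a spurious anisotropic component about 5% of the time.
#' @return A [MixtureFit-class]. Standard errors come from the inverse
#'   Gauss-Newton Hessian of the selected model's SSE at the optimum; when
#'   that matrix is singular they are reported as NA.
#' @export
fitMixture <- function(corr, lrtAlpha = 0.05, r2Gate = 0.1, ampGate = 1e-4,
                       dfExtra = 12L) {
  if (is(corr, "CorrelationMap")) {
    S <- surface(corr)
    lagF <- corr@lagFrames; lagS <- corr@lagSeconds
  } else {
    S <- corr
    lagF <- NA_integer_; lagS <- NA_real_
  }
  if (!all(is.finite(S))) stop("correlation surface must be finite")
  ax <- shiftAxes(S)
  XI <- matrix(ax$xi, length(ax$psi), length(ax$xi), byrow = TRUE)
  PSI <- matrix(ax$psi, length(ax$psi), length(ax$xi))
  y <- as.vector(S); XIv <- as.vector(XI); PSIv <- as.vector(PSI)
  maxShift <- max(abs(ax$xi))
  n <- length(y)

  # a component must be resolvable within the surface: cap sigmas at the
  # shift range so unidentifiable quasi-uniform pedestals and stripes cannot
  # pose as components (the uniform term epsilon covers those)
  sigMax <- maxShift
  isoLower <- c(-Inf, 0.2, -Inf); isoUpper <- c(Inf, sigMax, Inf)
  p0 <- isoSeed(S, XI, PSI)
  iso <- lmFit(y, XIv, PSIv, p0, isoLower, isoUpper)
  if (is.null(iso)) {
    return(new("MixtureFit", components = list(), epsilon = NA_real_,
               r2 = NA_real_, lrtP = NA_real_, classification = "noise",
               stderr = NA_real_, sse = NA_real_,
               lagFrames = lagF, lagSeconds = lagS, converged = FALSE))
  }
  fullLower <- c(isoLower, -Inf, -maxShift, -maxShift, 0.2, 0.2, -2 * pi)
  fullUpper <- c(isoUpper, Inf, maxShift, maxShift, sigMax, sigMax, 2 * pi)
  resid <- y - mixtureEval(iso$par, XIv, PSIv)
  seeds <- list(
    c(iso$par, anisoSeed(matrix(resid, nrow(S)), XI, PSI, maxShift)),
    c(iso$par, c(a2 = unname(iso$par[1]) * 0.1,
                 mux = XIv[which.max(resid)], muy = PSIv[which.max(resid)],
                 sM = 2, sm = 1, th = 0))
  )
  full <- NULL
  for (s0 in seeds) {
    cand <- lmFit(y, XIv, PSIv, s0, fullLower, fullUpper)
    if (!is.null(cand) && (is.null(full) || cand$sse < full$sse)) full <- cand
  }
  # evidence is counted in independent resolution cells, not raw points; the
  # noise correlation is estimated from the full-model residual so that true
  # anisotropic structure (absorbed by the full model) does not deflate it
  p <- if (is.null(full)) 1 else {
    residFull <- y - mixtureEval(full$par, XIv, PSIv)
    nEff <- round(effectivePoints(matrix(residFull, nrow(S))))
    if (nEff <= dfExtra + 3L) 1 else selectModel(iso$sse, full$sse, nEff, dfExtra)
  }
  useFull <- is.finite(p) && p < lrtAlpha && !is.null(full)
  sel <- if (useFull) full else iso
  parNames <- if (useFull) {
    c("a1", "sigma_iso", "epsilon", "a2", "mu_x", "mu_y",
      "sigma_major", "sigma_minor", "theta")
  } else c("a1", "sigma_iso", "epsilon")
  fitted <- mixtureEval(sel$par, XIv, PSIv)
  r2 <- rSquared(y, fitted)
  se <- sseStdErr(sel$residFn, sel$par, sel$sse)
  names(se) <- parNames

  comps <- list()
  a1 <- unname(sel$par[1])
  if (a1 > ampGate) {
    comps[[length(comps) + 1L]] <- new("GaussianComponent",
      amplitude = a1, center = c(0, 0),
      sigmaMajor = unname(sel$par[2]), sigmaMinor = unname(sel$par[2]),
      theta = 0, isIsotropic = TRUE)
  }
  if (useFull) {
    a2 <- unname(sel$par[4])
    sM <- unname(sel$par[7]); sm <- unname(sel$par[8])
    th <- unname(sel$par[9])
    if (sm > sM) { tmp <- sM; sM <- sm; sm <- tmp; th <- th + pi / 2 }
    th <- th %% pi
    if (a2 > ampGate) {
      comps[[length(comps) + 1L]] <- new("GaussianComponent",
        amplitude = a2, center = unname(sel$par[5:6]),
        sigmaMajor = sM, sigmaMinor = sm, theta = th, isIsotropic = FALSE)
    }
  }
  cls <- if (!is.finite(r2) || r2 <= r2Gate || !length(comps)) {
    "noise"
  } else if (any(!vapply(comps, function(k) k@isIsotropic, TRUE))) {
    "isotropic+anisotropic"
  } else "isotropic"
  new("MixtureFit", components = comps, epsilon = unname(sel$par[3]),
      r2 = if (is.finite(r2)) r2 else NA_real_,
      lrtP = p, classification = cls, stderr = se, sse = sel$sse,
      lagFrames = lagF, lagSeconds = lagS, converged = sel$converged)
}

#' Windowed kinetic map of mixture fits across a cell
#'
#' Runs the full mICS chain: photobleaching correction, removal of the
#' time-averaged image, spatiotemporal correlation in sliding windows, and a
#' mixture fit per window and lag.
#'
#' @param stack an [ImageStack-class].
#' @param windowSize,step window tiling (defaults 32 px windows, 16 px step:
#'   half-window overlap).
#' @param maxLag largest frame lag tau (default 20).
#' @param maxShift correlation shift range (default 8 px).
#' @param bleach apply [bleachCorrect()] first (default TRUE).
#' @param ... gates passed to [fitMixture()].
#' @return A [KineticMap-class]; see [as.data.frame.KineticMap()] for the
#'   long-format serialization.
#' @export
micsMap <- function(stack, windowSize = 32L, step = 16L, maxLag = 20L,
                    maxShift = 8L, bleach = TRUE, ...) {
  if (bleach) stack <- bleachCorrect(stack)
  fluct <- removeTimeAverage(stack)
  wins <- tileWindows(stack, windowSize, step)
  lags <- seq_len(as.integer(maxLag))
  fits <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    maps <- sticsCorrelate(fluct, wins[w, ], lags = lags, maxShift = maxShift)
    if (is(maps, "CorrelationMap")) maps <- list(maps)
    fits[[w]] <- lapply(maps, fitMixture, ...)
  }
  new("KineticMap", fits = fits, windows = wins,
      lags = as.integer(lags), meta = meta(stack))
}

#' Display record for a fitted component
#'
#' Converts a mixture fit into physical display quantities: the full width at
#' half maximum FWHM = 2 sqrt(2 ln 2) sigma in micrometres (circle diameter
#' for the isotropic component; cross-arm lengths along theta and
#' theta + pi/2 for the anisotropic component), with line weights
#' proportional to the relative component amplitudes.
#'
#' @param fit a [MixtureFit-class].
#' @param meta an [AcquisitionMeta-class] (pixel size).
#' @return A data.frame with one row per reported component (columns: type,
#'   fwhm_major_um, fwhm_minor_um, theta, center_x_um, center_y_um,
#'   rel_amplitude); zero rows for a noise classification.
#' @export
summarizeComponent <- function(fit, meta) {
  if (fit@classification == "noise" || !length(fit@components)) {
    return(data.frame(type = character(), fwhm_major_um = numeric(),
                      fwhm_minor_um = numeric(), theta = numeric(),
                      center_x_um = numeric(), center_y_um = numeric(),
                      rel_amplitude = numeric()))
  }
  k <- 2 * sqrt(2 * log(2)) * meta@pixelSize
  amps <- vapply(fit@components, function(g) g@amplitude, 1)
  do.call(rbind, lapply(seq_along(fit@components), function(i) {
    g <- fit@components[[i]]
    data.frame(
      type = if (g@isIsotropic) "isotropic" else "anisotropic",
      fwhm_major_um = k * g@sigmaMajor, fwhm_minor_um = k * g@sigmaMinor,
      theta = g@theta,
      center_x_um = g@center[1] * meta@pixelSize,
      center_y_um = g@center[2] * meta@pixelSize,
      rel_amplitude = amps[i] / sum(amps))
  }))
}

#' Diffusion coefficient from the lag dependence of the isotropic width
#'
#' Under free diffusion the isotropic correlation variance grows linearly
#' with lag: \eqn{\sigma^2(\tau) = \sigma_0^2 + 2 D \tau} (per axis). Fits a
#' straight line to \eqn{\sigma_{iso}^2} (converted to um^2) versus lag time
#' and returns D = slope / 2 with its standard error.
#'
#' Fit the line over the early, linear regime: once the fitted width grows
#' beyond roughly 40% of the correlation shift range, truncation of the
#' surface support biases the width downward and the law flattens; pass only
#' the early-lag fits (e.g. `fits[1:10]` for a +/-8 px surface).
#'
#' @param fits list of [MixtureFit-class] over lags (one window's series).
#' @param meta an [AcquisitionMeta-class].
#' @return list(D, stderr, nLags, intercept_um2).
#' @export
diffusionFromLagSeries <- function(fits, meta) {
  rows <- lapply(fits, function(f) {
    iso <- components(f, "isotropic")
    if (f@classification == "noise" || is.null(iso)) return(NULL)
    c(tau = f@lagSeconds, s2 = (iso@sigmaMajor * meta@pixelSize)^2)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) < 5L) {
    stop("need at least 5 lags with an isotropic component")
  }
  fit <- stats::lm(s2 ~ tau, data = as.data.frame(rows))
  sm <- summary(fit)$coefficients
  list(D = unname(sm["tau", "Estimate"]) / 2,
       stderr = unname(sm["tau", "Std. Error"]) / 2,
       nLags = nrow(rows),
       intercept_um2 = unname(sm["(Intercept)", "Estimate"]))
}
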