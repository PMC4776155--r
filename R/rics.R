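# Raster image correlation spectroscopy: normalized spatial autocorrelation
# and the raster-scan diffusion model fit.

#' Intensity-normalized spatial autocorrelation of one frame
#'
#' Computes
#' \deqn{G(\xi,\psi) = \langle I(x,y)\,I(x+\xi,y+\psi)\rangle_{x,y} / \langle I\rangle^2 - 1}
#' averaged over all in-bounds pixel pairs (non-periodic, per-shift pair-count
#' normalization; no circular wrap). At zero shift this equals the spatial
#' variance over the squared mean of the frame.
#'
#' @param frame numeric matrix of intensities with positive mean.
#' @param maxShiftCol,maxShiftRow maximum |xi| (column) and |psi| (row)
#'   shifts retained.
#' @return A matrix over (psi, xi) shifts, dimnames giving the shifts.
#' @export
spatialAutocorrelation <- function(frame, maxShiftCol = 16L, maxShiftRow = 8L) {
  m <- mean(frame)
  if (m <= 0) stop("frame mean must be positive for normalized correlation")
  num <- xcorrNumerator(frame, frame, maxShiftRow, maxShiftCol)
  cnt <- pairCounts(nrow(frame), ncol(frame), maxShiftRow, maxShiftCol)
  num / (cnt * m^2) - 1
}

#' Frame-averaged RICS correlation of a stack
#'
#' Optionally high-pass filters the stack (subtracting a centred moving
#' average over `highpass` frames, then re-offsetting by the grand mean
#' intensity so normalized correlation is defined), computes the normalized
#' spatial autocorrelation of every frame, and averages the surfaces
#' element-wise across frames.
#'
#' @param stack an [ImageStack-class].
#' @param window optional single window (one row of [tileWindows()] output or
#'   a list with row, col, size); default uses the full frame.
#' @param maxShiftCol,maxShiftRow shift range retained.
#' @param highpass moving-average length in frames for the temporal high-pass
#'   (default 10); 0 disables filtering.
#' @return A [RICSCorrelation-class].
#' @export
ricsAverage <- function(stack, window = NULL, maxShiftCol = 16L,
                        maxShiftRow = 8L, highpass = 10L) {
  fr <- frames(stack)
  if (!is.null(window)) {
    if (is.data.frame(window)) window <- as.list(window[1, ])
    fr <- windowSlab(fr, window)
  }
  T <- dim(fr)[1]; h <- dim(fr)[2]; w <- dim(fr)[3]
  maxShiftCol <- min(as.integer(maxShiftCol), w - 1L)
  maxShiftRow <- min(as.integer(maxShiftRow), h - 1L)
  if (highpass > 0) {
    if (T <= highpass) stop("stack shorter than the high-pass window")
    fr <- maHighpassRaw(fr, highpass) + mean(fr)
  }
  ph <- nextPow2(h + maxShiftRow)
  pw <- nextPow2(w + maxShiftCol)
  acc <- matrix(0 + 0i, ph, pw)
  pad <- matrix(0, ph, pw)
  for (t in seq_len(T)) {
    f <- matrix(fr[t, , ], h, w)
    m <- mean(f)
    if (m <= 0) stop("frame ", t, " has non-positive mean after preprocessing")
    pad[1:h, 1:w] <- f
    Ft <- stats::fft(pad)
    acc <- acc + (Conj(Ft) * Ft) / m^2
  }
  cc <- Re(stats::fft(acc, inverse = TRUE)) / (ph * pw * T)
  num <- wrapIndex(cc, maxShiftRow, maxShiftCol)
  cnt <- pairCounts(h, w, maxShiftRow, maxShiftCol)
  new("RICSCorrelation", surface = num / cnt - 1,
      nFramesAveraged = as.integer(T), meta = meta(stack))
}

#' Model surface of the raster-scan diffusion model
#'
#' The RICS model factors into a molecular-dynamics term and a scanning-optics
#' term, plus a constant background:
#' \deqn{G_{RICS}(\xi,\psi) = S(\xi,\psi)\,G(\xi,\psi) + b}
#' \deqn{G = \frac{\gamma}{N}\Big(1+\frac{4D\tau}{\omega_0^2}\Big)^{-1}\Big(1+\frac{4D\tau}{\omega_z^2}\Big)^{-1/2},\quad
#'       S = \exp\!\Big(-\frac{(\xi\,\delta r)^2+(\psi\,\delta r)^2}{\omega_0^2\,(1+4D\tau/\omega_0^2)}\Big)}
#' with \eqn{\tau = \tau_p|\xi| + \tau_l|\psi|} the scan-time offset of the
#' shifted pixel pair. The absolute values make the surface symmetric under
#' the non-periodic pair averaging used here.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param N particles in the focal volume.
#' @param b background offset.
#' @param meta an [AcquisitionMeta-class] (pixel size, dwell, line time).
#' @param gamma illumination shape factor (0.3536 for a 3D Gaussian volume).
#' @param omega0,omegaZ lateral/axial waists, um.
#' @param maxShiftCol,maxShiftRow shift range of the returned surface.
#' @return A matrix over (psi, xi) shifts.
#' @export
ricsModelSurface <- function(D, N, b, meta, gamma = 0.3536,
                             omega0 = meta@beamWaist, omegaZ = meta@axialWaist,
                             maxShiftCol = 16L, maxShiftRow = 8L) {
  xi <- -maxShiftCol:maxShiftCol
  psi <- -maxShiftRow:maxShiftRow
  XI <- matrix(xi, length(psi), length(xi), byrow = TRUE)
  PSI <- matrix(psi, length(psi), length(xi))
  S <- ricsModelEval(c(D, N, b), XI, PSI, meta, gamma, omega0, omegaZ)
  dimnames(S) <- list(psi = as.character(psi), xi = as.character(xi))
  S
}

# Evaluate the RICS model on shift grids (par = c(D, N, b)).
ricsModelEval <- function(par, XI, PSI, meta, gamma, omega0, omegaZ) {
  D <- par[1]; N <- par[2]; b <- par[3]
  tau <- meta@pixelDwell * abs(XI) + meta@lineTime * abs(PSI)
  g1 <- 1 + 4 * D * tau / omega0^2
  g2 <- 1 + 4 * D * tau / omegaZ^2
  dr2 <- (XI * meta@pixelSize)^2 + (PSI * meta@pixelSize)^2
  S <- exp(-dr2 / omega0^2 / g1)
  S * (gamma / N) / g1 / sqrt(g2) + b
}

#' Fit the raster-scan diffusion model to a RICS correlation
#'
#' Weighted least-squares fit of [ricsModelSurface()] to the measured
#' surface, with D, N and the background b free. The zero-shift point is
#' excluded by default (uncorrelated shot noise concentrates there) and the
#' fit region is restricted to small shifts where the model is informative.
#' Weights are the square roots of the per-shift pair counts. Initialization
#' is multi-start over D0 in \{0.1, 1, 10, 100\} um^2/s (best residual sum of
#' squares wins; ties go to the smaller D).
#'
#' @param corr a [RICSCorrelation-class].
#' @param gamma fixed illumination shape factor.
#' @param omega0,omegaZ calibration waists, um (defaults from the metadata).
#' @param fitShiftCol,fitShiftRow fit region half-widths, pixels.
#' @param excludeZero drop the (0,0) shot-noise point (default TRUE).
#' @return A [RICSFit-class] with parameter standard errors from the
#'   Gauss-Newton covariance at the optimum.
#' @export
fitRICS <- function(corr, gamma = 0.3536, omega0 = meta(corr)@beamWaist,
                    omegaZ = meta(corr)@axialWaist,
                    fitShiftCol = 16L, fitShiftRow = 8L, excludeZero = TRUE) {
  S <- surface(corr)
  ax <- shiftAxes(S)
  keepR <- abs(ax$psi) <= fitShiftRow
  keepC <- abs(ax$xi) <= fitShiftCol
  S <- S[keepR, keepC, drop = FALSE]
  psi <- ax$psi[keepR]; xi <- ax$xi[keepC]
  XI <- matrix(xi, length(psi), length(xi), byrow = TRUE)
  PSI <- matrix(psi, length(psi), length(xi))
  mask <- !(excludeZero & XI == 0 & PSI == 0)
  mt <- meta(corr)
  # pair-count weighting is nearly flat over this region for full frames;
  # unit weights keep the fit independent of the (unknown) source frame size
  y <- S[mask]; XIv <- XI[mask]; PSIv <- PSI[mask]; wv <- 1
  residFn <- function(par) {
    wv * (y - ricsModelEval(par, XIv, PSIv, mt, gamma, omega0, omegaZ))
  }
  g10 <- S[PSI == 0 & XI == 1]
  n0 <- gamma / max(g10 - min(S), 1e-6)
  starts <- lapply(c(0.1, 1, 10, 100), function(d0) {
    c(D = d0, N = max(n0, 1e-3), b = min(S))
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = residFn,
        lower = c(0, 1e-12, -Inf), upper = c(Inf, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && fit$par[1] < best$par[1])) {
      best <- list(par = fit$par, sse = sse,
                   converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) stop("RICS fit failed to converge from every start")
  par <- best$par
  fitted <- ricsModelEval(par, XIv, PSIv, mt, gamma, omega0, omegaZ)
  se <- sseStdErr(residFn, par, best$sse)
  names(se) <- c("D", "N", "b")
  new("RICSFit", D = unname(par[1]), N = unname(par[2]), b = unname(par[3]),
      gamma = gamma, omega0 = omega0, omegaZ = omegaZ,
      fitR2 = rSquared(y, fitted), stderr = se, converged = best$converged)
}
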