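# Synthetic raster-scanned confocal scenes: point emitters under the motion
# modes the correlation analyses are designed to detect, rendered through a
# Gaussian PSF with photon noise.

#' Motion model constructors
#'
#' Each constructor returns a [MotionModel-class] describing one motion mode
#' of the point emitters:
#' \describe{
#'   \item{diffusionModel}{free 2D Brownian motion, per-axis step variance
#'     2 D dt.}
#'   \item{boundModel}{binding with turnover, modelled as exchange with a
#'     fast-diffusing pool: each emitter has a fixed site that is occupied
#'     for an exponential residence time (mean `residenceTime` seconds),
#'     then vacant for an exponential `offTime` while the molecule diffuses
#'     too fast to correlate at the frame time scale (it is invisible to the
#'     slow-correlation analysis), then re-occupied. Sites switch
#'     independently of one another. `residenceTime = Inf` gives strictly
#'     static emitters, whose fluctuations vanish entirely once the time
#'     average is removed.}
#'   \item{confinedOscillatingModel}{diffusion inside a reflecting box of
#'     half-width `halfWidth` centred on the particle start; the +x wall
#'     oscillates as x0 + amplitude * sin(2 pi t / period).}
#'   \item{filamentOscillatingModel}{a rigid segment of static emitters
#'     (length um, orientation theta radians, centred in the frame unless
#'     `center` is given) translated perpendicular to its axis by
#'     amplitude * sin(2 pi t / period). nParticles of the scene are placed
#'     evenly along the segment.}
#'   \item{directedModel}{constant drift `velocity` (um/s, length-2 vector)
#'     plus optional diffusion D.}
#' }
#'
#' @param D diffusion coefficient, um^2/s.
#' @param residenceTime mean bound residence time, seconds (Inf = static).
#' @param offTime mean vacancy time of a site, seconds (default equal to the
#'   residence time: 50% duty cycle).
#' @param halfWidth confinement half-width, um.
#' @param amplitude oscillation amplitude, um.
#' @param period oscillation period, seconds (must exceed twice the frame
#'   interval to be resolvable).
#' @param theta filament orientation, radians (0 = along +x).
#' @param length filament length, um.
#' @param center optional filament centre (x, y) in um.
#' @param velocity drift velocity c(vx, vy), um/s.
#' @return A [MotionModel-class].
#' @name motionModels
NULL

#' @rdname motionModels
#' @export
diffusionModel <- function(D) {
  stopifnot(D >= 0)
  new("MotionModel", mode = "diffusion", params = list(D = D))
}

#' @rdname motionModels
#' @export
boundModel <- function(residenceTime = 10, offTime = residenceTime) {
  stopifnot(residenceTime > 0, offTime > 0 || !is.finite(residenceTime))
  new("MotionModel", mode = "bound",
      params = list(residenceTime = residenceTime, offTime = offTime))
}

#' @rdname motionModels
#' @export
confinedOscillatingModel <- function(D, halfWidth, amplitude, period) {
  stopifnot(D > 0, halfWidth > 0, amplitude > 0, period > 0)
  new("MotionModel", mode = "confined_oscillating",
      params = list(D = D, halfWidth = halfWidth,
                    amplitude = amplitude, period = period))
}

#' @rdname motionModels
#' @export
filamentOscillatingModel <- function(theta, length, amplitude, period,
                                     center = NULL) {
  stopifnot(length > 0, amplitude > 0, period > 0)
  new("MotionModel", mode = "filament_oscillating",
      params = list(theta = theta %% pi, length = length,
                    amplitude = amplitude, period = period, center = center))
}

#' @rdname motionModels
#' @export
directedModel <- function(velocity, D = 0) {
  stopifnot(length(velocity) == 2, D >= 0)
  new("MotionModel", mode = "directed",
      params = list(velocity = as.numeric(velocity), D = D))
}

#' Scene configuration
#'
#' @param nParticles number of emitters.
#' @param brightness expected counts per emitter per pixel dwell at the PSF
#'   centre.
#' @param width,height frame size in pixels.
#' @param nFrames number of frames.
#' @param meta an [AcquisitionMeta-class] (beam waist supplies the PSF).
#' @param poissonNoise apply photon noise (default TRUE).
#' @param gaussianSD additive read-noise standard deviation (counts).
#' @param margin field margin beyond the frame on each side, um (default
#'   6 beam waists; particles wrap periodically at the field edge so the
#'   density stays stationary).
#' @param seed RNG seed consumed by [simulateStack()] (NA = do not seed).
#' @return A [SceneConfig-class].
#' @export
sceneConfig <- function(nParticles, brightness, width, height, nFrames, meta,
                        poissonNoise = TRUE, gaussianSD = 0,
                        margin = 6 * meta@beamWaist, seed = NA_integer_) {
  new("SceneConfig",
      nParticles = as.integer(nParticles), brightness = as.numeric(brightness),
      width = as.integer(width), height = as.integer(height),
      nFrames = as.integer(nFrames), meta = meta,
      poissonNoise = isTRUE(poissonNoise), gaussianSD = as.numeric(gaussianSD),
      margin = as.numeric(margin), seed = as.integer(seed))
}

# mICS acquisition geometry (256 x 32 px, 100 nm/px, 1.27 us dwell,
# 49.6 ms/frame) as a convenience default.
#' Acquisition presets matching the supported imaging geometries
#'
#' `micsAcquisition()`: 100 nm pixels, 1.27 us dwell, 49.6 ms frame interval
#' (256 x 32 px geometry); `ricsAcquisition()`: 80 nm pixels, 6.3 us dwell
#' (128 x 128 px geometry), line time = width x dwell, contiguous frames.
#'
#' @param width frame width in pixels (sets the line time).
#' @param height frame height in pixels.
#' @param beamWaist lateral beam waist, um.
#' @return An [AcquisitionMeta-class].
#' @export
micsAcquisition <- function(width = 256L, height = 32L, beamWaist = 0.25) {
  lt <- width * 1.27e-6
  acquisitionMeta(pixelSize = 0.1, pixelDwell = 1.27e-6, lineTime = lt,
                  frameInterval = max(0.0496, height * lt),
                  beamWaist = beamWaist)
}

#' @rdname micsAcquisition
#' @export
ricsAcquisition <- function(width = 128L, height = 128L, beamWaist = 0.25) {
  lt <- width * 6.3e-6
  acquisitionMeta(pixelSize = 0.08, pixelDwell = 6.3e-6, lineTime = lt,
                  frameInterval = height * lt, beamWaist = beamWaist)
}

# field extent in um: frame plus margins; origin at the first pixel centre
fieldExtent <- function(config) {
  px <- config@meta@pixelSize
  list(
    xmin = -config@margin, xmax = (config@width - 1) * px + config@margin,
    ymin = -config@margin, ymax = (config@height - 1) * px + config@margin
  )
}

# sample times covering the acquisition
frameTimes <- function(config) (seq_len(config@nFrames) - 1) * config@meta@frameInterval
lineTimes <- function(config) {
  f <- rep(frameTimes(config), each = config@height)
  f + rep((seq_len(config@height) - 1) * config@meta@lineTime, config@nFrames)
}

#' Simulate emitter trajectories on an acquisition time base
#'
#' Positions are generated at the frame start times (`sampling = "frame"`) or
#' at every scan-line start time (`sampling = "line"`, required by
#' [renderRaster()] so that particles move during the scan). Diffusive steps
#' are Gaussian with per-axis variance 2 D dt between consecutive sample
#' times; directed motion adds v dt; confined modes reflect at the (possibly
#' oscillating) boundary; bound particles are static between relocation
#' events. Free and directed particles wrap periodically at the field edge.
#'
#' This function consumes the current RNG stream; use [simulateStack()] for
#' seeded, reproducible scene generation.
#'
#' @param model a [MotionModel-class].
#' @param config a [SceneConfig-class].
#' @param sampling "frame" or "line".
#' @return A [Trajectories-class].
#' @export
simulateTrajectories <- function(model, config,
                                 sampling = c("frame", "line")) {
  sampling <- match.arg(sampling)
  times <- if (sampling == "frame") frameTimes(config) else lineTimes(config)
  nT <- length(times)
  ext <- fieldExtent(config)
  nP <- config@nParticles
  pos <- array(0, c(nT, nP, 2))
  wrap <- function(x, lo, hi) lo + (x - lo) %% (hi - lo)
  startX <- stats::runif(nP, ext$xmin, ext$xmax)
  startY <- stats::runif(nP, ext$ymin, ext$ymax)
  dt <- diff(times)

  if (model@mode == "diffusion" || model@mode == "directed") {
    D <- if (!is.null(model@params$D)) model@params$D else 0
    v <- if (model@mode == "directed") model@params$velocity else c(0, 0)
    for (ax in 1:2) {
      sd <- sqrt(2 * D * dt)
      steps <- matrix(stats::rnorm(length(dt) * nP), length(dt), nP) * sd +
        v[ax] * dt
      start <- if (ax == 1) startX else startY
      csum <- apply(steps, 2, cumsum)
      if (is.null(dim(csum))) csum <- matrix(csum, length(dt), nP)
      p <- rbind(start, sweep(csum, 2, -start))
      dimnames(p) <- NULL
      lo <- if (ax == 1) ext$xmin else ext$ymin
      hi <- if (ax == 1) ext$xmax else ext$ymax
      pos[, , ax] <- wrap(p, lo, hi)
    }
  } else if (model@mode == "bound") {
    rt <- model@params$residenceTime
    ot <- model@params$offTime
    tEnd <- times[nT]
    for (i in seq_len(nP)) {
      pos[, i, 1] <- startX[i]
      pos[, i, 2] <- startY[i]
      if (!is.finite(rt)) next
      # independent ON/OFF telegraph occupancy per site (exchange with a
      # fast-diffusing pool that is invisible at the frame time scale);
      # stationary initial state, alternating exponential durations
      duty <- rt / (rt + ot)
      on <- stats::runif(1) < duty
      nEv <- max(16L, ceiling(4 * tEnd * (1 / rt + 1 / ot)))
      dur <- numeric(nEv)
      state <- on
      for (k in seq_len(nEv)) {
        dur[k] <- stats::rexp(1, rate = if (state) 1 / rt else 1 / ot)
        state <- !state
      }
      sw <- cumsum(dur)
      seg <- findInterval(times, sw)              # 0-based segment index
      occupied <- if (on) seg %% 2L == 0L else seg %% 2L == 1L
      pos[!occupied, i, 1] <- NA_real_
      pos[!occupied, i, 2] <- NA_real_
    }
  } else if (model@mode == "confined_oscillating") {
    D <- model@params$D; hw <- model@params$halfWidth
    A <- model@params$amplitude; P <- model@params$period
    for (i in seq_len(nP)) {
      x <- startX[i]; y <- startY[i]
      pos[1, i, ] <- c(x, y)
      for (k in seq_along(dt)) {
        sd <- sqrt(2 * D * dt[k])
        x <- x + stats::rnorm(1, 0, sd)
        y <- y + stats::rnorm(1, 0, sd)
        # box walls around the start; +x wall oscillates
        xmax <- startX[i] + hw + A * sin(2 * pi * times[k + 1] / P)
        xmin <- startX[i] - hw
        ymin <- startY[i] - hw; ymax <- startY[i] + hw
        x <- reflectInto(x, xmin, xmax)
        y <- reflectInto(y, ymin, ymax)
        pos[k + 1, i, ] <- c(x, y)
      }
    }
  } else if (model@mode == "filament_oscillating") {
    th <- model@params$theta; L <- model@params$length
    A <- model@params$amplitude; P <- model@params$period
    ctr <- model@params$center
    if (is.null(ctr)) {
      px <- config@meta@pixelSize
      ctr <- c((config@width - 1) * px / 2, (config@height - 1) * px / 2)
    }
    u <- c(cos(th), sin(th))           # along the filament
    nvec <- c(-sin(th), cos(th))       # perpendicular (oscillation axis)
    s <- seq(-L / 2, L / 2, length.out = nP)
    off <- A * sin(2 * pi * times / P)
    for (i in seq_len(nP)) {
      pos[, i, 1] <- ctr[1] + s[i] * u[1] + off * nvec[1]
      pos[, i, 2] <- ctr[2] + s[i] * u[2] + off * nvec[2]
    }
  } else {
    stop("unknown motion mode: ", model@mode)
  }
  new("Trajectories", times = times, positions = pos,
      sampling = sampling, model = model)
}

# reflect a scalar into [lo, hi]
reflectInto <- function(x, lo, hi) {
  span <- hi - lo
  if (span <= 0) return(lo)
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  lo + y
}

# Core renderer: given per-frame (perLine = FALSE) or per-line positions,
# paint Gaussian PSF spots. Positions beyond cutoff = 3.5 w0 are skipped.
renderScene <- function(traj, config, perLine) {
  mt <- config@meta
  px <- mt@pixelSize
  w0 <- mt@beamWaist
  B <- config@brightness
  W <- config@width; H <- config@height; nF <- config@nFrames
  cutoff <- 3.5 * w0
  xc <- (seq_len(W) - 1) * px
  yc <- (seq_len(H) - 1) * px
  out <- array(0, c(nF, H, W))
  nP <- dim(traj@positions)[2]
  for (f in seq_len(nF)) {
    img <- matrix(0, H, W)
    if (perLine) {
      rows0 <- (f - 1L) * H
      PX <- traj@positions[rows0 + seq_len(H), , 1, drop = FALSE]
      PY <- traj@positions[rows0 + seq_len(H), , 2, drop = FALSE]
      for (i in seq_len(nP)) {
        pyr <- PY[, i, 1]                     # particle y at each line time
        rows <- which(is.finite(pyr) & abs(yc - pyr) <= cutoff)
        if (!length(rows)) next
        pxr <- PX[rows, i, 1]
        cmin <- max(1L, floor((min(pxr) - cutoff) / px) + 1L)
        cmax <- min(W, ceiling((max(pxr) + cutoff) / px) + 1L)
        if (cmin > cmax) next
        cols <- cmin:cmax
        dx <- outer(-pxr, xc[cols], "+")
        dy <- yc[rows] - pyr[rows]
        img[rows, cols] <- img[rows, cols] +
          B * exp(-2 * (dx^2 + dy^2) / w0^2)
      }
    } else {
      for (i in seq_len(nP)) {
        pxi <- traj@positions[f, i, 1]
        pyi <- traj@positions[f, i, 2]
        if (!is.finite(pxi)) next             # vacant site (unbound emitter)
        rows <- which(abs(yc - pyi) <= cutoff)
        cols <- which(abs(xc - pxi) <= cutoff)
        if (!length(rows) || !length(cols)) next
        ey <- exp(-2 * (yc[rows] - pyi)^2 / w0^2)
        ex <- exp(-2 * (xc[cols] - pxi)^2 / w0^2)
        img[rows, cols] <- img[rows, cols] + B * outer(ey, ex)
      }
    }
    out[f, , ] <- img
  }
  if (config@poissonNoise) {
    out[] <- stats::rpois(length(out), lambda = out)
  }
  if (config@gaussianSD > 0) {
    out <- out + stats::rnorm(length(out), 0, config@gaussianSD)
    out[out < 0] <- 0
  }
  imageStack(out, mt, "synthetic")
}

#' Render trajectories through the raster scan
#'
#' `renderRaster()` evaluates every scan line at its own acquisition time
#' (line `r` of frame `f` at t = f frameInterval + r lineTime), so particles
#' move *during* the scan -- the time structure RICS exploits. It requires
#' line-sampled trajectories. `renderFrames()` snapshots all pixels of a
#' frame at the frame start time, a fast approximation valid when the motion
#' per frame is small against the PSF (the mICS regime).
#'
#' Pixel values are brightness-weighted Gaussian PSF amplitudes
#' exp(-2 d^2 / w0^2) summed over emitters, with optional Poisson photon
#' noise and Gaussian read noise. Both functions consume the RNG stream (for
#' the noise); see [simulateStack()] for seeded generation.
#'
#' @param traj a [Trajectories-class] (line-sampled for `renderRaster`).
#' @param config the [SceneConfig-class] used for the trajectories.
#' @return An [ImageStack-class].
#' @export
renderRaster <- function(traj, config) {
  if (traj@sampling != "line") {
    stop("renderRaster needs line-sampled trajectories ",
         "(simulateTrajectories(..., sampling = 'line'))")
  }
  if (dim(traj@positions)[1] != config@nFrames * config@height) {
    stop("trajectory time base does not match the scan geometry")
  }
  renderScene(traj, config, perLine = TRUE)
}

#' @rdname renderRaster
#' @export
renderFrames <- function(traj, config) {
  if (traj@sampling != "frame") stop("renderFrames needs frame-sampled trajectories")
  if (dim(traj@positions)[1] != config@nFrames) {
    stop("trajectory time base does not match the frame count")
  }
  renderScene(traj, config, perLine = FALSE)
}

# Fast path for frame-rendered bound scenes: site positions are fixed, so
# the noise-free image changes only where occupancy switches. Maintains a
# running image and adds/subtracts single-site PSF blobs per frame, which
# makes realistic site densities (tens of thousands) affordable.
renderBoundFast <- function(model, config) {
  mt <- config@meta
  px <- mt@pixelSize; w0 <- mt@beamWaist; B <- config@brightness
  W <- config@width; H <- config@height; nF <- config@nFrames
  cutoff <- 3.5 * w0
  xc <- (seq_len(W) - 1) * px
  yc <- (seq_len(H) - 1) * px
  ext <- fieldExtent(config)
  nP <- config@nParticles
  sx <- stats::runif(nP, ext$xmin, ext$xmax)
  sy <- stats::runif(nP, ext$ymin, ext$ymax)
  rt <- model@params$residenceTime
  ot <- model@params$offTime
  times <- frameTimes(config)
  occ <- matrix(TRUE, nF, nP)
  if (is.finite(rt)) {
    duty <- rt / (rt + ot)
    tEnd <- times[nF]
    nEv <- max(16L, ceiling(4 * tEnd * (1 / rt + 1 / ot)))
    for (i in seq_len(nP)) {
      on <- stats::runif(1) < duty
      dur <- stats::rexp(nEv, rate = 1 / rt)
      off <- stats::rexp(nEv, rate = 1 / ot)
      sw <- cumsum(as.vector(rbind(if (on) dur else off,
                                   if (on) off else dur)))
      seg <- findInterval(times, sw)
      occ[, i] <- if (on) seg %% 2L == 0L else seg %% 2L == 1L
    }
  }
  blob <- function(img, i, sign) {
    rows <- which(abs(yc - sy[i]) <= cutoff)
    cols <- which(abs(xc - sx[i]) <= cutoff)
    if (length(rows) && length(cols)) {
      ey <- exp(-2 * (yc[rows] - sy[i])^2 / w0^2)
      ex <- exp(-2 * (xc[cols] - sx[i])^2 / w0^2)
      img[rows, cols] <- img[rows, cols] + sign * B * outer(ey, ex)
    }
    img
  }
  out <- array(0, c(nF, H, W))
  img <- matrix(0, H, W)
  for (i in which(occ[1, ])) img <- blob(img, i, 1)
  out[1, , ] <- img
  for (f in 2:nF) {
    flips <- which(occ[f, ] != occ[f - 1, ])
    for (i in flips) img <- blob(img, i, if (occ[f, i]) 1 else -1)
    out[f, , ] <- img
  }
  out[out < 0] <- 0          # float dust from incremental subtraction
  if (config@poissonNoise) out[] <- stats::rpois(length(out), lambda = out)
  if (config@gaussianSD > 0) {
    out <- out + stats::rnorm(length(out), 0, config@gaussianSD)
    out[out < 0] <- 0
  }
  imageStack(out, mt, "synthetic")
}

#' Simulate a complete synthetic stack (seeded)
#'
#' Seeds the RNG from `config@seed` (when not NA), simulates trajectories and
#' renders them, so that an identical configuration yields a bit-identical
#' stack.
#'
#' @param model a [MotionModel-class].
#' @param config a [SceneConfig-class].
#' @param sampling "frame" (snapshot renderer) or "line" (raster renderer).
#' @return An [ImageStack-class].
#' @export
simulateStack <- function(model, config, sampling = c("frame", "line")) {
  sampling <- match.arg(sampling)
  if (!is.na(config@seed)) set.seed(config@seed)
  if (model@mode == "bound" && sampling == "frame") {
    return(renderBoundFast(model, config))
  }
  traj <- simulateTrajectories(model, config, sampling)
  if (sampling == "line") renderRaster(traj, config)
  else renderFrames(traj, config)
}
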