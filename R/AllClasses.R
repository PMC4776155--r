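#' @import methods
NULL

#' Acquisition metadata for a raster-scanned image stack
#'
#' Holds the timing and optical calibration of a confocal raster scan. All
#' correlation analyses interpret pixel shifts through these constants: the
#' pixel size sets the spatial scale, the pixel dwell and line times set the
#' intra-frame time structure exploited by RICS, and the frame interval sets
#' the lag-time axis of spatiotemporal correlation. The beam waist is the
#' 1/e^2 radius of the Gaussian excitation profile.
#'
#' @slot pixelSize pixel size in micrometres per pixel.
#' @slot pixelDwell pixel dwell time in seconds.
#' @slot lineTime time between the starts of consecutive scan lines, seconds.
#' @slot frameInterval time between the starts of consecutive frames, seconds.
#' @slot beamWaist lateral beam waist (1/e^2 radius) in micrometres.
#' @slot axialWaist axial waist in micrometres (used only by the RICS model).
#'
#' @export
setClass("AcquisitionMeta",
  representation(
    pixelSize     = "numeric",
    pixelDwell    = "numeric",
    lineTime      = "numeric",
    frameInterval = "numeric",
    beamWaist     = "numeric",
    axialWaist    = "numeric"
  )
)

setValidity("AcquisitionMeta", function(object) {
  v <- c(
    pixelSize = object@pixelSize, pixelDwell = object@pixelDwell,
    lineTime = object@lineTime, frameInterval = object@frameInterval,
    beamWaist = object@beamWaist, axialWaist = object@axialWaist
  )
  if (any(!is.finite(v)) || any(v <= 0)) {
    return("all acquisition metadata fields must be finite and strictly positive")
  }
  if (object@lineTime > object@frameInterval) {
    return("lineTime cannot exceed frameInterval")
  }
  TRUE
})

#' A time-ordered stack of 2D fluorescence frames
#'
#' The universal input of the package: a 3D array of non-negative intensities
#' ordered (time, row, column) together with its acquisition metadata.
#'
#' @slot frames numeric array with dim (nFrames, nRows, nCols), finite, >= 0.
#' @slot meta an [AcquisitionMeta-class] object.
#' @slot channelLabel character label for the fluorescence channel.
#'
#' @export
setClass("ImageStack",
  representation(
    frames       = "array",
    meta         = "AcquisitionMeta",
    channelLabel = "character"
  )
)

setValidity("ImageStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3D array (time, row, col)")
  if (d[1] < 2L) return("an ImageStack needs at least 2 frames")
  if (!all(is.finite(object@frames))) return("intensities must be finite")
  if (min(object@frames) < 0) return("intensities must be non-negative")
  m <- object@meta
  if (m@lineTime < d[3] * m@pixelDwell - 1e-12) {
    return("lineTime must be at least width * pixelDwell")
  }
  if (m@frameInterval < d[2] * m@lineTime - 1e-12) {
    return("frameInterval must be at least height * lineTime")
  }
  TRUE
})

#' A stack of zero-time-mean intensity fluctuations
#'
#' Produced by [removeTimeAverage()] (and consumed by [sticsCorrelate()]):
#' the per-pixel time average has been subtracted, so only moving or
#' fluctuating emitters contribute. The removed time-average image is kept so
#' raw window mean intensities can be reconstructed for correlation
#' normalization.
#'
#' @slot deltas numeric array (time, row, col) of fluctuations; per-pixel time
#'   mean is ~0.
#' @slot meanImage the removed per-pixel time-average image (row, col).
#' @slot meanIntensity per-frame spatial mean intensity of the source stack.
#' @slot meta the source [AcquisitionMeta-class].
#'
#' @export
setClass("FluctuationStack",
  representation(
    deltas        = "array",
    meanImage     = "matrix",
    meanIntensity = "numeric",
    meta          = "AcquisitionMeta"
  )
)

setValidity("FluctuationStack", function(object) {
  d <- dim(object@deltas)
  if (length(d) != 3L) return("deltas must be a 3D array (time, row, col)")
  if (!all(dim(object@meanImage) == d[2:3])) {
    return("meanImage must match the frame shape")
  }
  if (length(object@meanIntensity) != d[1]) {
    return("meanIntensity must have one value per frame")
  }
  scale <- max(abs(object@meanImage), 1e-12)
  mx <- max(abs(apply(object@deltas, c(2, 3), mean)))
  if (mx > 1e-9 * scale) {
    return("per-pixel time mean of deltas must vanish")
  }
  TRUE
})

#' Frame-averaged RICS spatial autocorrelation surface
#'
#' @slot surface matrix over row shifts psi (rows) and column shifts xi
#'   (columns), centred at zero shift; dimnames carry the shifts.
#' @slot nFramesAveraged number of frames averaged.
#' @slot meta acquisition metadata of the source stack.
#'
#' @export
setClass("RICSCorrelation",
  representation(
    surface         = "matrix",
    nFramesAveraged = "integer",
    meta            = "AcquisitionMeta"
  )
)

setValidity("RICSCorrelation", function(object) {
  if (!all(is.finite(object@surface))) return("surface must be finite")
  if (any(dim(object@surface) %% 2L != 1L)) {
    return("surface must have odd dimensions (centred at zero shift)")
  }
  TRUE
})

#' Fitted RICS diffusion model
#'
#' Result of [fitRICS()]: the raster-scan diffusion model parameters and fit
#' diagnostics.
#'
#' @slot D diffusion coefficient, um^2/s.
#' @slot N mean number of particles in the focal volume.
#' @slot b constant background/offset term.
#' @slot gamma illumination shape factor (fixed, not fitted).
#' @slot omega0,omegaZ lateral and axial waists used by the model, um.
#' @slot fitR2 coefficient of determination over the fit region.
#' @slot stderr named standard errors for D, N, b (NA when unavailable).
#' @slot converged logical convergence flag.
#'
#' @export
setClass("RICSFit",
  representation(
    D = "numeric", N = "numeric", b = "numeric",
    gamma = "numeric", omega0 = "numeric", omegaZ = "numeric",
    fitR2 = "numeric", stderr = "numeric", converged = "logical"
  )
)

setValidity("RICSFit", function(object) {
  if (object@D < 0) return("D must be >= 0")
  if (object@N <= 0) return("N must be > 0")
  if (object@fitR2 > 1 + 1e-12) return("fitR2 cannot exceed 1")
  TRUE
})

#' Spatiotemporal correlation surface at one frame lag
#'
#' Average cross-correlation of intensity fluctuations over all frame pairs
#' separated by a fixed lag, as a function of the spatial shifts
#' (xi = column shift, psi = row shift).
#'
#' @slot surface matrix over (psi, xi), odd dimensions, centred at zero shift.
#' @slot lagFrames lag in frames (>= 1).
#' @slot lagSeconds lag in seconds (lagFrames * frameInterval).
#' @slot nPairs number of frame pairs averaged.
#' @slot meta acquisition metadata.
#'
#' @export
setClass("CorrelationMap",
  representation(
    surface    = "matrix",
    lagFrames  = "integer",
    lagSeconds = "numeric",
    nPairs     = "integer",
    meta       = "AcquisitionMeta"
  )
)

setValidity("CorrelationMap", function(object) {
  if (any(dim(object@surface) %% 2L != 1L)) {
    return("surface must have odd dimensions (centred at zero shift)")
  }
  if (!all(is.finite(object@surface))) return("surface must be finite")
  if (object@lagFrames < 1L) return("lagFrames must be >= 1")
  TRUE
})

#' One Gaussian component of a mixture fit
#'
#' Isotropic components are centred circular Gaussians (the signature of
#' diffusion or binding); anisotropic components may be offset and elongated
#' (the signature of confined motion along a structure).
#'
#' @slot amplitude component amplitude (a1 or a2).
#' @slot center (xi, psi) centre in pixels; (0, 0) for isotropic components.
#' @slot sigmaMajor,sigmaMinor Gaussian standard deviations in pixels along
#'   the major/minor axes; equal for isotropic components.
#' @slot theta major-axis orientation in radians, in [0, pi); 0 for isotropic.
#' @slot isIsotropic logical flag.
#'
#' @export
setClass("GaussianComponent",
  representation(
    amplitude  = "numeric",
    center     = "numeric",
    sigmaMajor = "numeric",
    sigmaMinor = "numeric",
    theta      = "numeric",
    isIsotropic = "logical"
  )
)

setValidity("GaussianComponent", function(object) {
  if (length(object@center) != 2L) return("center must be (xi, psi)")
  if (object@sigmaMajor <= 0 || object@sigmaMinor <= 0) {
    return("sigmas must be positive")
  }
  if (object@isIsotropic) {
    if (any(object@center != 0) ||
        abs(object@sigmaMajor - object@sigmaMinor) > 1e-12 ||
        object@theta != 0) {
      return("isotropic component must be centred, circular, theta = 0")
    }
  }
  TRUE
})

#' Two-component Gaussian mixture fit of a correlation surface
#'
#' The fit of an isotropic Gaussian, an optional anisotropic Gaussian, and a
#' spatially uniform noise floor to one [CorrelationMap-class]. Model
#' selection (isotropic vs isotropic + anisotropic) is by a one-sided
#' likelihood-ratio test; surfaces with R^2 <= 0.1 are classified as noise,
#' and a component is reported only when its amplitude exceeds 1e-4.
#'
#' @slot components list of 0-2 [GaussianComponent-class] objects (the
#'   reported components, after gating).
#' @slot epsilon fitted uniform noise level.
#' @slot r2 coefficient of determination of the selected model.
#' @slot lrtP one-sided likelihood-ratio p-value for the anisotropic term.
#' @slot classification one of "noise", "isotropic", "isotropic+anisotropic".
#' @slot stderr named per-parameter standard errors from the inverse Hessian
#'   of the selected model (NA when the Hessian is singular).
#' @slot sse residual sum of squares of the selected model.
#' @slot lagFrames,lagSeconds lag of the fitted surface.
#' @slot converged logical convergence flag.
#'
#' @export
setClass("MixtureFit",
  representation(
    components = "list",
    epsilon    = "numeric",
    r2         = "numeric",
    lrtP       = "numeric",
    classification = "character",
    stderr     = "numeric",
    sse        = "numeric",
    lagFrames  = "integer",
    lagSeconds = "numeric",
    converged  = "logical"
  )
)

setValidity("MixtureFit", function(object) {
  ok <- c("noise", "isotropic", "isotropic+anisotropic")
  if (!object@classification %in% ok) {
    return(sprintf("classification must be one of %s", paste(ok, collapse = ", ")))
  }
  if (is.finite(object@lrtP) && (object@lrtP < 0 || object@lrtP > 1)) {
    return("lrtP must lie in [0, 1]")
  }
  if (length(object@components) > 2L) return("at most 2 components")
  TRUE
})

#' Windowed map of mixture fits across a cell
#'
#' The kinetic map: for every analysis window tiled across the frame and
#' every lag tau = 1..maxLag, one [MixtureFit-class].
#'
#' @slot fits list (one element per window) of lists (one per lag) of
#'   [MixtureFit-class].
#' @slot windows data.frame of window origins (row, col, 1-based) and size.
#' @slot lags integer vector of lags in frames.
#' @slot meta acquisition metadata.
#'
#' @export
setClass("KineticMap",
  representation(
    fits    = "list",
    windows = "data.frame",
    lags    = "integer",
    meta    = "AcquisitionMeta"
  )
)

setValidity("KineticMap", function(object) {
  if (length(object@fits) != nrow(object@windows)) {
    return("one fit series per window required")
  }
  if (!all(vapply(object@fits, length, 1L) == length(object@lags))) {
    return("all fit series must share the lag axis")
  }
  TRUE
})

#' Pixel-shift Pearson correlation between two channels
#'
#' @slot rp matrix of Pearson coefficients over row shifts (rows) and column
#'   shifts (columns); dimnames carry the shifts.
#' @slot channels character pair of channel labels.
#'
#' @export
setClass("ShiftCorrelation",
  representation(rp = "matrix", channels = "character")
)

setValidity("ShiftCorrelation", function(object) {
  v <- object@rp[is.finite(object@rp)]
  if (length(v) && (min(v) < -1 - 1e-12 || max(v) > 1 + 1e-12)) {
    return("Pearson coefficients must lie in [-1, 1]")
  }
  TRUE
})

#' Kymograph: intensity along a path versus time
#'
#' @slot matrix intensity matrix (position along path x time), one column per
#'   frame, positions ordered from the path start.
#' @slot path data.frame of the polyline vertices (row, col), pixel units.
#' @slot spacing micrometres between consecutive samples along the path.
#'
#' @export
setClass("Kymograph",
  representation(matrix = "matrix", path = "data.frame", spacing = "numeric")
)

#' Result of the 1D translocation Monte Carlo
#'
#' @slot positions matrix (time step + 1) x particles of cytoplasmic positions
#'   in micrometres from the nuclear envelope; NA once absorbed.
#' @slot times recording times in seconds (0, dt, ..., tMax).
#' @slot nuclearCount per-time cumulative count of absorbed particles.
#' @slot cytoFraction per-time fraction of particles still cytoplasmic.
#' @slot config the configuration list used (echo).
#'
#' @export
setClass("TranslocationResult",
  representation(
    positions    = "matrix",
    times        = "numeric",
    nuclearCount = "integer",
    cytoFraction = "numeric",
    config       = "list"
  )
)

setValidity("TranslocationResult", function(object) {
  if (any(diff(object@nuclearCount) < 0L)) {
    return("nuclearCount must be non-decreasing (one-way sink)")
  }
  n <- ncol(object@positions)
  alive <- rowSums(!is.na(object@positions))
  if (any(alive + object@nuclearCount != n)) {
    return("cytoplasmic + nuclear counts must equal the particle number")
  }
  p <- object@positions[!is.na(object@positions)]
  if (length(p) && (min(p) < 0 || max(p) > object@config$length + 1e-9)) {
    return("positions must lie in [0, length]")
  }
  TRUE
})

#' Motion model for the synthetic-scene simulator
#'
#' @slot mode one of "diffusion", "bound", "confined_oscillating",
#'   "filament_oscillating", "directed".
#' @slot params named list of mode parameters (see the constructors).
#'
#' @seealso [diffusionModel()], [boundModel()], [confinedOscillatingModel()],
#'   [filamentOscillatingModel()], [directedModel()]
#' @export
setClass("MotionModel",
  representation(mode = "character", params = "list")
)

#' Scene configuration for the synthetic-scene simulator
#'
#' @slot nParticles number of emitters.
#' @slot brightness expected photon counts per emitter per pixel dwell at the
#'   beam centre.
#' @slot width,height frame size in pixels.
#' @slot nFrames number of frames.
#' @slot meta acquisition metadata ([AcquisitionMeta-class]).
#' @slot poissonNoise logical, apply photon (Poisson) noise.
#' @slot gaussianSD standard deviation of additive read noise (counts).
#' @slot margin simulation field margin beyond the frame on each side, um.
#' @slot seed integer RNG seed (NA for none).
#'
#' @export
setClass("SceneConfig",
  representation(
    nParticles = "integer", brightness = "numeric",
    width = "integer", height = "integer", nFrames = "integer",
    meta = "AcquisitionMeta",
    poissonNoise = "logical", gaussianSD = "numeric",
    margin = "numeric", seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  if (object@nParticles < 1L) return("nParticles must be >= 1")
  if (object@brightness <= 0) return("brightness must be positive")
  if (object@width < 2L || object@height < 1L) return("frame too small")
  if (object@nFrames < 2L) return("need at least 2 frames")
  if (object@gaussianSD < 0) return("gaussianSD must be >= 0")
  TRUE
})

#' Particle trajectories sampled on an acquisition time base
#'
#' @slot times sample times in seconds (frame starts or line starts).
#' @slot positions array (nTimes, nParticles, 2) of (x, y) in micrometres;
#'   NA marks a vacant bound site (emitter unbound, invisible).
#' @slot sampling "frame" or "line".
#' @slot model the generating [MotionModel-class].
#'
#' @export
setClass("Trajectories",
  representation(
    times = "numeric", positions = "array",
    sampling = "character", model = "MotionModel"
  )
)
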