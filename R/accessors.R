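# Generics, accessors and show methods for the core containers.

#' Construct acquisition metadata
#'
#' @param pixelSize pixel size, micrometres per pixel.
#' @param pixelDwell pixel dwell time, seconds.
#' @param lineTime time between scan-line starts, seconds. Defaults to a
#'   contiguous scan is not assumed; supply the instrument value.
#' @param frameInterval time between frame starts, seconds.
#' @param beamWaist lateral 1/e^2 beam waist, micrometres.
#' @param axialWaist axial waist, micrometres (default 3 x beamWaist).
#' @return An [AcquisitionMeta-class] object.
#' @examples
#' acquisitionMeta(pixelSize = 0.1, pixelDwell = 1.27e-6,
#'                 lineTime = 4e-4, frameInterval = 0.0496)
#' @export
acquisitionMeta <- function(pixelSize, pixelDwell, lineTime, frameInterval,
                            beamWaist = 0.25, axialWaist = 3 * beamWaist) {
  new("AcquisitionMeta",
      pixelSize = as.numeric(pixelSize), pixelDwell = as.numeric(pixelDwell),
      lineTime = as.numeric(lineTime), frameInterval = as.numeric(frameInterval),
      beamWaist = as.numeric(beamWaist), axialWaist = as.numeric(axialWaist))
}

#' Construct an image stack
#'
#' @param frames 3D numeric array ordered (time, row, col), or a list of
#'   equally sized matrices (one per frame).
#' @param meta an [AcquisitionMeta-class].
#' @param channelLabel channel name.
#' @return An [ImageStack-class].
#' @export
imageStack <- function(frames, meta, channelLabel = "ch1") {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE))) {
      stop("all frames must have the same shape")
    }
    arr <- array(0, c(length(frames), d[1], d[2]))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    frames <- arr
  }
  new("ImageStack", frames = frames, meta = meta, channelLabel = channelLabel)
}

#' @describeIn imageStack number of frames.
#' @param x,object an object.
#' @export
nFrames <- function(x) dim(frames(x))[1]

#' Extract the frame array or metadata
#'
#' `frames()` returns the (time, row, col) array of an [ImageStack-class] or
#' the fluctuation array of a [FluctuationStack-class]; `meta()` returns the
#' attached [AcquisitionMeta-class].
#'
#' @param x the container.
#' @return `frames()`: a 3D array; `meta()`: an [AcquisitionMeta-class].
#' @export
frames <- function(x) {
  if (is(x, "ImageStack")) x@frames
  else if (is(x, "FluctuationStack")) x@deltas
  else stop("no frames in an object of class ", class(x))
}

#' @rdname frames
#' @export
meta <- function(x) {
  if (is(x, "ImageStack") || is(x, "FluctuationStack") ||
      is(x, "RICSCorrelation") || is(x, "CorrelationMap") ||
      is(x, "KineticMap")) x@meta
  else if (is(x, "SceneConfig")) x@meta
  else stop("no acquisition metadata in an object of class ", class(x))
}

#' @rdname frames
#' @export
surface <- function(x) {
  if (is(x, "RICSCorrelation") || is(x, "CorrelationMap")) x@surface
  else stop("no correlation surface in an object of class ", class(x))
}

#' Classification of a mixture fit
#' @param x a [MixtureFit-class].
#' @export
classification <- function(x) x@classification

#' Components of a mixture fit
#'
#' @param x a [MixtureFit-class].
#' @param type "isotropic", "anisotropic" or "all".
#' @return A [GaussianComponent-class], a list of them, or NULL.
#' @export
components <- function(x, type = c("all", "isotropic", "anisotropic")) {
  type <- match.arg(type)
  if (type == "all") return(x@components)
  iso <- vapply(x@components, function(k) k@isIsotropic, TRUE)
  hit <- x@components[if (type == "isotropic") iso else !iso]
  if (length(hit)) hit[[1]] else NULL
}

setMethod("show", "AcquisitionMeta", function(object) {
  cat("AcquisitionMeta:",
      sprintf("%.4g um/px, dwell %.3g s, line %.3g s, frame %.3g s, w0 %.3g um\n",
              object@pixelSize, object@pixelDwell, object@lineTime,
              object@frameInterval, object@beamWaist))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack '%s': %d frames of %d x %d px (%.3g um/px, %.3g s/frame)\n",
              object@channelLabel, d[1], d[2], d[3],
              object@meta@pixelSize, object@meta@frameInterval))
})

setMethod("show", "FluctuationStack", function(object) {
  d <- dim(object@deltas)
  cat(sprintf("FluctuationStack: %d frames of %d x %d px (zero time-mean)\n",
              d[1], d[2], d[3]))
})

setMethod("show", "RICSCorrelation", function(object) {
  d <- dim(object@surface)
  cat(sprintf("RICSCorrelation: shifts psi +/-%d, xi +/-%d, %d frames averaged\n",
              (d[1] - 1L) %/% 2L, (d[2] - 1L) %/% 2L, object@nFramesAveraged))
})

setMethod("show", "RICSFit", function(object) {
  cat(sprintf("RICSFit: D = %.4g um^2/s, N = %.4g, b = %.3g (R2 = %.3f%s)\n",
              object@D, object@N, object@b, object@fitR2,
              if (object@converged) "" else ", NOT converged"))
})

setMethod("show", "CorrelationMap", function(object) {
  d <- dim(object@surface)
  cat(sprintf("CorrelationMap: lag %d frames (%.4g s), shifts +/-%d px, %d pairs\n",
              object@lagFrames, object@lagSeconds,
              (d[2] - 1L) %/% 2L, object@nPairs))
})

setMethod("show", "GaussianComponent", function(object) {
  if (object@isIsotropic) {
    cat(sprintf("GaussianComponent (isotropic): a = %.4g, sigma = %.3g px\n",
                object@amplitude, object@sigmaMajor))
  } else {
    cat(sprintf(
      "GaussianComponent (anisotropic): a = %.4g, centre (%.2f, %.2f) px, sigma %.3g/%.3g px, theta %.1f deg\n",
      object@amplitude, object@center[1], object@center[2],
      object@sigmaMajor, object@sigmaMinor, object@theta * 180 / pi))
  }
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit (lag %d): %s, R2 = %.3f, LRT p = %.3g, eps = %.3g\n",
              object@lagFrames, object@classification, object@r2,
              object@lrtP, object@epsilon))
  for (k in object@components) show(k)
})

setMethod("show", "KineticMap", function(object) {
  cat(sprintf("KineticMap: %d windows x %d lags\n",
              nrow(object@windows), length(object@lags)))
})

setMethod("show", "ShiftCorrelation", function(object) {
  cat(sprintf("ShiftCorrelation %s vs %s over %d x %d shifts; r_p(0,0) = %.3f\n",
              object@channels[1], object@channels[2],
              nrow(object@rp), ncol(object@rp),
              object@rp[(nrow(object@rp) + 1L) %/% 2L,
                        (ncol(object@rp) + 1L) %/% 2L]))
})

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph: %d samples x %d frames (%.3g um spacing)\n",
              nrow(object@matrix), ncol(object@matrix), object@spacing))
})

setMethod("show", "TranslocationResult", function(object) {
  n <- ncol(object@positions)
  cat(sprintf(
    "TranslocationResult: %d particles, %d steps; nuclear fraction %.3f at t = %g s\n",
    n, length(object@times) - 1L,
    utils::tail(object@nuclearCount, 1) / n, utils::tail(object@times, 1)))
})

setMethod("show", "MotionModel", function(object) {
  cat("MotionModel:", object@mode, "\n")
  str(object@params, give.attr = FALSE)
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d emitters, %d x %d px x %d frames, brightness %.3g\n",
              object@nParticles, object@height, object@width, object@nFrames,
              object@brightness))
})

#' Coerce a kinetic map to a long-format data frame
#'
#' One row per window and lag, with the fitted parameters, gates and
#' diagnostics; the serialization used by the command-line interface.
#'
#' @param x a [KineticMap-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return A data.frame with columns window_row, window_col, window_size,
#'   lag_frames, lag_s, classification, a1, sigma_iso, a2, mu_x, mu_y,
#'   sigma_major, sigma_minor, theta, epsilon, r2, lrt_p, converged.
#' @export
as.data.frame.KineticMap <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- list()
  for (w in seq_len(nrow(x@windows))) {
    for (l in seq_along(x@lags)) {
      f <- x@fits[[w]][[l]]
      iso <- components(f, "isotropic")
      ani <- components(f, "anisotropic")
      rows[[length(rows) + 1L]] <- data.frame(
        window_row = x@windows$row[w], window_col = x@windows$col[w],
        window_size = x@windows$size[w],
        lag_frames = f@lagFrames, lag_s = f@lagSeconds,
        classification = f@classification,
        a1 = if (!is.null(iso)) iso@amplitude else NA_real_,
        sigma_iso = if (!is.null(iso)) iso@sigmaMajor else NA_real_,
        a2 = if (!is.null(ani)) ani@amplitude else NA_real_,
        mu_x = if (!is.null(ani)) ani@center[1] else NA_real_,
        mu_y = if (!is.null(ani)) ani@center[2] else NA_real_,
        sigma_major = if (!is.null(ani)) ani@sigmaMajor else NA_real_,
        sigma_minor = if (!is.null(ani)) ani@sigmaMinor else NA_real_,
        theta = if (!is.null(ani)) ani@theta else NA_real_,
        epsilon = f@epsilon, r2 = f@r2, lrt_p = f@lrtP,
        converged = f@converged
      )
    }
  }
  do.call(rbind, rows)
}
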