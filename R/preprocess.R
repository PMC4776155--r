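# Photobleaching correction and static-structure removal.

#' Photobleaching correction preserving frame mean and variance
#'
#' Rescales every frame so that both the spatial mean and the variance of a
#' shot-noise-limited signal stay at their initial values over the course of
#' the acquisition:
#' \deqn{I'(x,y,t) = I(x,y,t)/\sqrt{f(t)/f(0)} + f(0)\,(1 - \sqrt{f(t)/f(0)})}
#' where \eqn{f(t)} is the spatial mean intensity of frame \eqn{t}. The
#' corrected frame mean equals \eqn{f(0)} exactly; for Poisson-distributed
#' intensities (variance = mean) the corrected variance is also stabilized at
#' its initial level.
#'
#' @param stack an [ImageStack-class] with positive frame means.
#' @return A corrected [ImageStack-class]. Already-flat stacks are returned
#'   unchanged (the correction is idempotent on them).
#' @export
bleachCorrect <- function(stack) {
  fr <- frames(stack)
  f <- apply(fr, 1, mean)
  if (any(f <= 0)) stop("bleach correction undefined: a frame has zero spatial mean")
  s <- sqrt(f / f[1])
  out <- fr / s + rep(f[1] * (1 - s), times = prod(dim(fr)[2:3]))
  # negative values can only arise from numerical round-off here
  out[out < 0] <- 0
  initialize(stack, frames = out)
}

#' Remove the time-averaged image
#'
#' Subtracts the per-pixel time average, removing immobile structure so that
#' correlations reflect only moving or fluctuating emitters.
#'
#' @param stack an [ImageStack-class] (at least 2 frames).
#' @return A [FluctuationStack-class] whose per-pixel time mean is zero; the
#'   removed average image and the per-frame spatial means are retained for
#'   correlation normalization.
#' @export
removeTimeAverage <- function(stack) {
  fr <- frames(stack)
  avg <- apply(fr, c(2, 3), mean)
  deltas <- fr - rep(avg, each = dim(fr)[1])
  new("FluctuationStack",
      deltas = deltas, meanImage = avg,
      meanIntensity = apply(fr, 1, mean), meta = meta(stack))
}

#' Moving-average temporal high-pass filter
#'
#' Subtracts a centred moving average over `window` frames from every pixel's
#' time trace, removing slow drifts (e.g. whole-cell movement) while keeping
#' fast fluctuations. At the stack edges the averaging window shrinks
#' symmetrically. The output fluctuates around the local mean (no offset is
#' re-added); see [ricsAverage()] for how RICS restores a positive mean
#' before normalized correlation.
#'
#' @param stack an [ImageStack-class].
#' @param window moving-average length in frames (default 10).
#' @return A [FluctuationStack-class] of local-mean-removed fluctuations.
#'   Note its per-pixel *global* time mean is near, but not exactly, zero;
#'   the stored meanImage is the global time average for reference.
#' @export
movingAverageHighpass <- function(stack, window = 10L) {
  fr <- frames(stack)
  T <- dim(fr)[1]
  window <- as.integer(window)
  if (T <= window) stop("stack shorter than the moving-average window")
  deltas <- maHighpassRaw(fr, window)
  # remove the (small) residual DC so the output is a true fluctuation stack
  new("FluctuationStack",
      deltas = deltas - rep(apply(deltas, c(2, 3), mean), each = T),
      meanImage = apply(fr, c(2, 3), mean),
      meanIntensity = apply(fr, 1, mean), meta = meta(stack))
}

# Local-mean fluctuations without the exact re-centring (internal: RICS path
# keeps the raw high-passed values and re-offsets by the grand mean).
maHighpassRaw <- function(fr, window) {
  T <- dim(fr)[1]
  half <- as.integer(window) %/% 2L
  cs <- apply(fr, c(2, 3), cumsum)
  idx <- seq_len(T)
  shrink <- pmin(idx - pmax(idx - half, 1L), pmin(idx + half, T) - idx)
  lo <- idx - shrink
  hi <- idx + shrink
  n <- hi - lo + 1L
  csLo <- cs[pmax(lo - 1L, 1L), , , drop = FALSE]
  csLo[lo == 1L, , ] <- 0
  ma <- (cs[hi, , , drop = FALSE] - csLo) / rep(n, times = prod(dim(fr)[2:3]))
  fr - ma
}
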