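# Pixel-shift Pearson co-localization and kymograph extraction.

#' Pixel-shift Pearson correlation between two channels
#'
#' For every shift (dx, dy) on the grid, computes the Pearson correlation
#' coefficient between channel R and channel G displaced by that shift,
#' over the overlapping pixels only (shifted-out pixels are excluded, not
#' zero-padded, so each r is a genuine paired-pixel Pearson coefficient).
#' The auto-correlation of any image at zero shift is exactly 1.
#'
#' @param chanR,chanG numeric matrices of equal shape.
#' @param shifts integer vector of shifts applied along both axes
#'   (default -4:4, giving the full 9 x 9 grid).
#' @param channels character pair of labels.
#' @return A [ShiftCorrelation-class]; entries with zero-variance overlap are
#'   NA.
#' @examples
#' img <- matrix(runif(100), 10)
#' rp <- pearsonShift(img, img)
#' rp@rp["0", "0"]  # exactly 1
#' @export
pearsonShift <- function(chanR, chanG, shifts = -4:4,
                         channels = c("R", "G")) {
  stopifnot(identical(dim(chanR), dim(chanG)))
  h <- nrow(chanR); w <- ncol(chanR)
  shifts <- as.integer(shifts)
  if (max(abs(shifts)) >= min(h, w)) stop("shift exceeds image size")
  rp <- matrix(NA_real_, length(shifts), length(shifts),
               dimnames = list(dy = as.character(shifts),
                               dx = as.character(shifts)))
  for (iy in seq_along(shifts)) {
    for (ix in seq_along(shifts)) {
      dy <- shifts[iy]; dx <- shifts[ix]
      r1 <- max(1L, 1L - dy):min(h, h - dy)
      c1 <- max(1L, 1L - dx):min(w, w - dx)
      a <- chanR[r1, c1]
      b <- chanG[r1 + dy, c1 + dx]
      if (identical(a, b)) {
        rp[iy, ix] <- 1          # self correlation is exactly 1 by definition
      } else if (stats::sd(a) > 0 && stats::sd(b) > 0) {
        rp[iy, ix] <- stats::cor(as.vector(a), as.vector(b))
      }
    }
  }
  new("ShiftCorrelation", rp = rp, channels = channels)
}

#' Extract a kymograph along a path
#'
#' Samples each frame by bilinear interpolation at `nSamples` equally spaced
#' points along a polyline (e.g. from the nuclear edge to the cell edge) and
#' assembles the position x time intensity matrix.
#'
#' @param stack an [ImageStack-class].
#' @param path data.frame or matrix of polyline vertices with columns
#'   (row, col), 1-based pixel coordinates (fractional allowed).
#' @param nSamples number of samples along the path (>= 2).
#' @return A [Kymograph-class]; `spacing` is the micrometre distance between
#'   consecutive samples.
#' @export
extractKymograph <- function(stack, path, nSamples = 100L) {
  fr <- frames(stack)
  h <- dim(fr)[2]; w <- dim(fr)[3]
  path <- as.data.frame(path)
  if (!all(c("row", "col") %in% names(path))) {
    colnames(path)[1:2] <- c("row", "col")
  }
  if (nrow(path) < 2L) stop("path needs at least 2 vertices")
  if (min(path$row) < 1 || max(path$row) > h ||
      min(path$col) < 1 || max(path$col) > w) {
    stop("path exits the frame bounds")
  }
  nSamples <- as.integer(nSamples)
  if (nSamples < 2L) stop("nSamples must be >= 2")
  # arc-length parameterization of the polyline
  seg <- sqrt(diff(path$row)^2 + diff(path$col)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("path has zero length")
  at <- seq(0, total, length.out = nSamples)
  ridx <- stats::approx(s, path$row, xout = at)$y
  cidx <- stats::approx(s, path$col, xout = at)$y
  # bilinear interpolation weights (exact at integer lattice points)
  r0 <- pmin(floor(ridx), h - 1L); c0 <- pmin(floor(cidx), w - 1L)
  fr1 <- ridx - r0; fc1 <- cidx - c0
  T <- dim(fr)[1]
  out <- matrix(0, nSamples, T)
  for (t in seq_len(T)) {
    f <- matrix(fr[t, , ], h, w)
    out[, t] <-
      f[cbind(r0, c0)] * (1 - fr1) * (1 - fc1) +
      f[cbind(r0 + 1L, c0)] * fr1 * (1 - fc1) +
      f[cbind(r0, c0 + 1L)] * (1 - fr1) * fc1 +
      f[cbind(r0 + 1L, c0 + 1L)] * fr1 * fc1
  }
  new("Kymograph", matrix = out, path = path,
      spacing = total / (nSamples - 1) * meta(stack)@pixelSize)
}
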