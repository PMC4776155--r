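# Reading/writing image stacks and windowing geometry.

#' Read a multi-frame TIFF into an ImageStack
#'
#' Frames are returned in acquisition order. Acquisition metadata is not
#' parsed from microscope headers; supply it explicitly or as a YAML/JSON
#' sidecar via [readAcquisitionMeta()].
#'
#' @param path path to a multi-frame grayscale TIFF (8/16-bit or float).
#' @param meta an [AcquisitionMeta-class], or a path to a YAML/JSON sidecar.
#' @param channelLabel channel name to attach.
#' @param scale for integer TIFFs, the intensity scale: stored sample values
#'   (which the tiff reader maps to [0, 1]) are multiplied by `scale` and
#'   rounded, recovering the original integer counts. Ignored for float data.
#' @return An [ImageStack-class].
#' @seealso [writeStack()]
#' @export
readStack <- function(path, meta, channelLabel = "ch1", scale = 65535) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.character(meta)) meta <- readAcquisitionMeta(meta)
  fr <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(fr)) fr <- list(fr)
  if (length(fr) < 2L) stop("fewer than 2 frames in ", path)
  d <- dim(fr[[1]])
  if (length(d) != 2L) stop("only single-channel grayscale stacks are supported")
  if (!all(vapply(fr, function(f) identical(dim(f), d), TRUE))) {
    stop("non-uniform frame shapes in ", path)
  }
  att <- attr(fr[[1]], "bits.per.sample")
  isFloat <- identical(attr(fr[[1]], "sample.format"), "float")
  arr <- array(0, c(length(fr), d[1], d[2]))
  for (i in seq_along(fr)) {
    f <- fr[[i]]
    arr[i, , ] <- if (isFloat) f else round(f * scale)
  }
  imageStack(arr, meta, channelLabel)
}

#' Write an ImageStack to a multi-frame TIFF
#'
#' Integer output (the default) stores `round(intensity)` as 16-bit samples,
#' so a write/read round trip is bit-identical for integer data with values
#' below `scale`. Float output preserves arbitrary intensities at 32-bit
#' precision.
#'
#' @param stack an [ImageStack-class].
#' @param path output file path.
#' @param format "int16" or "float".
#' @param scale full-scale value for integer output.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, format = c("int16", "float"), scale = 65535) {
  format <- match.arg(format)
  fr <- frames(stack)
  n <- dim(fr)[1]
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fr[i, , , drop = TRUE]
    if (!is.matrix(f)) f <- matrix(f, dim(fr)[2], dim(fr)[3])
    frames[[i]] <- if (format == "int16") f / scale else f
  }
  if (format == "int16") {
    if (max(fr) > scale) stop("intensities exceed the integer scale ", scale)
    tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read/write acquisition metadata sidecar files
#'
#' Metadata travel next to the TIFF as a small YAML (or JSON) file with keys
#' pixel_size_um, pixel_dwell_s, line_time_s, frame_interval_s,
#' beam_waist_um, axial_waist_um.
#'
#' @param path sidecar file path (.yaml/.yml/.json).
#' @return [readAcquisitionMeta()]: an [AcquisitionMeta-class];
#'   [writeAcquisitionMeta()]: `path`, invisibly.
#' @export
readAcquisitionMeta <- function(path) {
  if (!file.exists(path)) stop("no such metadata file: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("pixel_size_um", "pixel_dwell_s", "line_time_s", "frame_interval_s")
  miss <- setdiff(need, names(vals))
  if (length(miss)) stop("metadata missing fields: ", paste(miss, collapse = ", "))
  acquisitionMeta(
    pixelSize = vals$pixel_size_um, pixelDwell = vals$pixel_dwell_s,
    lineTime = vals$line_time_s, frameInterval = vals$frame_interval_s,
    beamWaist = if (!is.null(vals$beam_waist_um)) vals$beam_waist_um else 0.25,
    axialWaist = if (!is.null(vals$axial_waist_um)) vals$axial_waist_um
                 else 3 * (if (!is.null(vals$beam_waist_um)) vals$beam_waist_um else 0.25)
  )
}

#' @rdname readAcquisitionMeta
#' @param meta an [AcquisitionMeta-class] to serialize.
#' @export
writeAcquisitionMeta <- function(meta, path) {
  vals <- list(
    pixel_size_um = meta@pixelSize, pixel_dwell_s = meta@pixelDwell,
    line_time_s = meta@lineTime, frame_interval_s = meta@frameInterval,
    beam_waist_um = meta@beamWaist, axial_waist_um = meta@axialWaist
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' Tile square analysis windows across a frame
#'
#' Windows cover the frame left-to-right, top-to-bottom on a regular grid
#' with the given step; windows that would overrun the frame edge are
#' dropped (no partial windows). With `step < size` neighbouring windows
#' overlap (e.g. size 32, step 16 gives half-window overlap).
#'
#' @param x an [ImageStack-class], [FluctuationStack-class], or an integer
#'   vector c(nRows, nCols).
#' @param size window side length in pixels.
#' @param step grid step in pixels (1 <= step <= size).
#' @return A data.frame with columns row, col (1-based origin of each
#'   window) and size.
#' @examples
#' tileWindows(c(32, 256), size = 32, step = 16)  # 15 windows along x
#' @export
tileWindows <- function(x, size, step = size) {
  d <- if (is.numeric(x)) as.integer(x[1:2]) else dim(frames(x))[2:3]
  size <- as.integer(size); step <- as.integer(step)
  if (size > min(d)) {
    stop(sprintf("window size %d exceeds the frame (%d x %d)", size, d[1], d[2]))
  }
  if (step < 1L || step > size) stop("step must satisfy 1 <= step <= size")
  rows <- seq.int(1L, d[1] - size + 1L, by = step)
  cols <- seq.int(1L, d[2] - size + 1L, by = step)
  out <- expand.grid(col = cols, row = rows)[, c("row", "col")]
  out$size <- size
  rownames(out) <- NULL
  out
}

# Extract one window's sub-array from a (time, row, col) array.
windowSlab <- function(arr, win) {
  r <- win$row; c <- win$col; s <- win$size
  arr[, r:(r + s - 1L), c:(c + s - 1L), drop = FALSE]
}
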