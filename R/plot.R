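# Schematic overlay of a kinetic map on the mean image.

#' Overlay fitted components on the mean image
#'
#' Draws the mean image of the stack with, at each analysis window centre,
#' the tau = 1 fit: a circle whose diameter is the isotropic FWHM and, when
#' an anisotropic component is reported, a cross whose arms are the FWHM
#' along the major and minor axes at the fitted orientation. Line weights
#' scale with the relative component amplitudes; noise windows are left
#' unmarked.
#'
#' @param km a [KineticMap-class].
#' @param stack the source [ImageStack-class] (for the mean image).
#' @param lag which lag to display (default 1).
#' @param file optional PNG path; when given the plot is written there.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the data.frame of drawn components.
#' @export
plotKineticMap <- function(km, stack, lag = 1L, file = NULL, ...) {
  avg <- apply(frames(stack), c(2, 3), mean)
  h <- nrow(avg); w <- ncol(avg)
  if (!is.null(file)) {
    grDevices::png(file, width = 160 * 8, height = max(160, 160 * 8 * h / w))
    on.exit(grDevices::dev.off())
  }
  graphics::par(mar = c(2, 2, 1, 1))
  graphics::image(x = seq_len(w), y = seq_len(h), z = t(avg)[, h:1],
                  col = grDevices::gray.colors(256, 0, 1), useRaster = TRUE,
                  xlab = "", ylab = "", asp = 1, ...)
  drawn <- list()
  li <- match(as.integer(lag), km@lags)
  if (is.na(li)) stop("lag not present in the kinetic map")
  px <- km@meta@pixelSize
  for (wi in seq_len(nrow(km@windows))) {
    f <- km@fits[[wi]][[li]]
    rec <- summarizeComponent(f, km@meta)
    if (!nrow(rec)) next
    cx <- km@windows$col[wi] + km@windows$size[wi] / 2
    cy <- h - (km@windows$row[wi] + km@windows$size[wi] / 2) + 1
    for (i in seq_len(nrow(rec))) {
      lwd <- 0.5 + 3 * rec$rel_amplitude[i]
      if (rec$type[i] == "isotropic") {
        r <- rec$fwhm_major_um[i] / px / 2
        tt <- seq(0, 2 * pi, length.out = 64)
        graphics::lines(cx + r * cos(tt), cy + r * sin(tt),
                        col = "red", lwd = lwd)
      } else {
        thM <- rec$theta[i]
        aM <- rec$fwhm_major_um[i] / px / 2
        am <- rec$fwhm_minor_um[i] / px / 2
        graphics::segments(cx - aM * cos(thM), cy - aM * sin(thM),
                           cx + aM * cos(thM), cy + aM * sin(thM),
                           col = "yellow", lwd = lwd)
        graphics::segments(cx + am * sin(thM), cy - am * cos(thM),
                           cx - am * sin(thM), cy + am * cos(thM),
                           col = "yellow", lwd = lwd)
      }
      drawn[[base::length(drawn) + 1L]] <- cbind(window = wi, rec[i, ])
    }
  }
  invisible(if (base::length(drawn)) do.call(rbind, drawn) else NULL)
}
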