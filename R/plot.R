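afm_palette <- function(n = 256L) {
  grDevices::colorRampPalette(c("#1a0f00", "#7a3b00", "#d98a2b", "#ffd9a0"))(n)
}

#' Display a height image
#'
#' Standard AFM-style rendering: origin at the top left, amber height
#' palette, optional contour overlays.
#'
#' @param x a `height_image`.
#' @param contours optional list of `afm_contour` objects to overlay.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.height_image <- function(x, contours = NULL, main = NULL, ...) {
  m <- x$heights
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[nrow(m):1L, , drop = FALSE]),
                  col = afm_palette(), asp = 1, xlab = "col (px)",
                  ylab = "row (px)", main = main, useRaster = TRUE, ...)
  if (!is.null(contours))
    for (cc in contours)
      graphics::lines(cc$points[, 2L], nrow(m) + 1L - cc$points[, 1L],
                      col = "#00c0ff", lwd = 2)
  invisible(x)
}

#' @export
plot.afm_profile <- function(x, ...) {
  graphics::plot(x$positions_nm, x$heights, type = "l",
                 xlab = "position (nm)", ylab = "height (nm)", ...)
  invisible(x)
}

#' Display a flattening result
#'
#' Two panels: the estimated background surface and the flattened image.
#' @param x a `flatten_result`.
#' @param ... passed on to the image plots.
#' @return Invisibly, `x`.
#' @export
plot.flatten_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(op))
  plot(x$background_est, main = paste0("background (", x$method, ")"), ...)
  plot(x$flattened, main = "flattened", ...)
  invisible(x)
}

#' @export
plot.foreground_mask <- function(x, ...) {
  m <- x$included * 1
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[nrow(m):1L, , drop = FALSE]),
                  col = c("black", "white"), asp = 1,
                  xlab = "col (px)", ylab = "row (px)", useRaster = TRUE, ...)
  invisible(x)
}
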