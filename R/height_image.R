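#' Height image container
#'
#' An AFM height map: a rectangular grid of heights in nanometres with a
#' pixel size and a record of which index runs along the fast-scan
#' direction. By convention each matrix row is one scan line, i.e. the fast
#' axis is the column index (`fast_axis = "cols"`, the default); use
#' [transpose_image()] or `fast_axis = "rows"` for data stored the other
#' way round.
#'
#' @param heights numeric matrix of heights in nm; all values must be finite.
#' @param pixel_size_nm positive scalar, lateral size of one pixel in nm.
#' @param fast_axis `"cols"` (each row is a scan line, default) or `"rows"`.
#' @return An object of class `height_image`: a list with elements
#'   `heights`, `pixel_size_nm`, `fast_axis`.
#' @examples
#' img <- height_image(matrix(rnorm(64), 8, 8), pixel_size_nm = 10)
#' dim(img)
#' @export
height_image <- function(heights, pixel_size_nm = 1, fast_axis = c("cols", "rows")) {
  fast_axis <- match.arg(fast_axis)
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("`heights` must be a numeric matrix", call. = FALSE)
  if (anyNA(heights) || any(!is.finite(heights))) {
    bad <- which(!is.finite(heights), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite height at (row %d, col %d)", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a positive scalar", call. = FALSE)
  storage.mode(heights) <- "double"
  structure(list(heights = heights,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 fast_axis = fast_axis),
            class = "height_image")
}

#' @export
dim.height_image <- function(x) dim(x$heights)

#' @export
as.matrix.height_image <- function(x, ...) x$heights

#' Coerce to a height image
#'
#' Accepts a `height_image` (returned unchanged) or a numeric matrix.
#' @param x object to coerce.
#' @param ... passed to [height_image()] for matrix input.
#' @return A `height_image`.
#' @export
as_height_image <- function(x, ...) {
  if (inherits(x, "height_image")) return(x)
  if (is.matrix(x)) return(height_image(x, ...))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to height_image", call. = FALSE)
}

#' @export
print.height_image <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf("<height_image> %d x %d px, pixel %.4g nm, fast axis: %s\n",
              d[1L], d[2L], x$pixel_size_nm, x$fast_axis))
  cat(sprintf("  height range: [%.4g, %.4g] nm\n",
              min(x$heights), max(x$heights)))
  invisible(x)
}

# replace the height grid, keeping metadata
set_heights <- function(img, m) {
  img$heights <- m
  img
}

#' Transpose a height image
#'
#' Swaps the two axes and flips the `fast_axis` label so the physical
#' fast-scan direction is preserved.
#' @param img a `height_image`.
#' @return The transposed `height_image`.
#' @export
transpose_image <- function(img) {
  img <- as_height_image(img)
  img$heights <- t(img$heights)
  img$fast_axis <- if (img$fast_axis == "cols") "rows" else "cols"
  img
}

#' Rotate a height image by 90 degrees clockwise
#'
#' Emulates re-scanning the same field with the slow and fast axes swapped:
#' the `fast_axis` label is deliberately kept, so drift that accumulated
#' along the slow axis now runs along the nominal fast direction.
#' @param img a `height_image`.
#' @return The rotated `height_image`.
#' @export
rotate_image_90 <- function(img) {
  img <- as_height_image(img)
  m <- img$heights
  img$heights <- t(m[nrow(m):1L, , drop = FALSE])
  img
}

#' Complement of a height image
#'
#' Returns `max(img) - img` elementwise. Concave features (pits) become
#' convex in the complement, which is how the segmentation step detects
#' them with the same outward-expanding contour machinery.
#' @param img a `height_image` or numeric matrix.
#' @return A `height_image` of the same shape.
#' @export
complement_image <- function(img) {
  img <- as_height_image(img)
  set_heights(img, max(img$heights) - img$heights)
}

# require a minimum size before any fitting operation
check_fit_size <- function(img, min_px = 4L) {
  d <- dim(img$heights)
  if (d[1L] < min_px || d[2L] < min_px)
    stop(sprintf("image must be at least %d x %d for fitting (got %d x %d)",
                 min_px, min_px, d[1L], d[2L]), call. = FALSE)
  invisible(img)
}
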