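#' Read a height image from disk
#'
#' Supported formats: single-channel 32-bit float TIFF (heights stored
#' directly in nm) and plain text matrices (whitespace- or comma-delimited,
#' one image row per line). `format = "auto"` picks TIFF for `.tif`/`.tiff`
#' extensions and text otherwise.
#'
#' @param path file path.
#' @param format `"auto"`, `"tiff"` or `"text"`.
#' @param pixel_size_nm pixel size to attach (neither format stores it).
#' @param fast_axis fast-axis convention to attach, see [height_image()].
#' @return A `height_image`.
#' @seealso [write_height_image()]
#' @export
read_height_image <- function(path, format = c("auto", "tiff", "text"),
                              pixel_size_nm = 1, fast_axis = "cols") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "text"
  m <- if (format == "tiff") read_tiff_matrix(path) else read_text_matrix(path)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite value at (row %d, col %d) in %s",
                 bad[1L, 1L], bad[1L, 2L], path), call. = FALSE)
  height_image(m, pixel_size_nm = pixel_size_nm, fast_axis = fast_axis)
}

#' Write a height image to disk
#'
#' TIFF output is a single-strip, uncompressed, single-channel 32-bit
#' IEEE-float TIFF holding the heights in nm (values are not rescaled);
#' text output is one whitespace-delimited image row per line at full
#' double precision. Both round-trip through [read_height_image()], TIFF
#' to within float32 precision and text to within double precision.
#'
#' @param img a `height_image` or numeric matrix.
#' @param path output file path.
#' @param format `"auto"`, `"tiff"` or `"text"`.
#' @return Invisibly, `path`.
#' @export
write_height_image <- function(img, path, format = c("auto", "tiff", "text")) {
  img <- as_height_image(img)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "text"
  if (format == "tiff") write_tiff_float32(img$heights, path)
  else write_text_matrix(img$heights, path)
  invisible(path)
}

read_text_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty text matrix: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[,[:space:]]+")
  lens <- lengths(toks)
  if (length(unique(lens)) != 1L)
    stop(sprintf("non-rectangular grid in %s: row 1 has %d cells, row %d has %d",
                 path, lens[1L], which(lens != lens[1L])[1L],
                 lens[which(lens != lens[1L])[1L]]), call. = FALSE)
  vals <- suppressWarnings(lapply(toks, as.numeric))
  for (i in seq_along(vals)) {
    j <- which(is.na(vals[[i]]) & !(toupper(toks[[i]]) %in% c("NA", "NAN")))
    if (length(j) > 0L)
      stop(sprintf("non-numeric cell '%s' at (row %d, col %d) in %s",
                   toks[[i]][j[1L]], i, j[1L], path), call. = FALSE)
  }
  do.call(rbind, vals)
}

write_text_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
}

read_tiff_matrix <- function(path) {
  r <- tiff::readTIFF(path, as.is = FALSE, all = FALSE)
  if (is.array(r) && length(dim(r)) == 3L) r <- r[, , 1L]
  if (!is.matrix(r)) stop("not a single-channel TIFF: ", path, call. = FALSE)
  r
}

# Minimal single-strip uncompressed grayscale float32 TIFF (little-endian).
# Values are written as-is (nm), unlike integer TIFF paths that rescale.
write_tiff_float32 <- function(m, path) {
  nr <- nrow(m); nc <- ncol(m)
  data_bytes <- 4L * nr * nc
  ifd_offset <- 8L + data_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeChar("II", con, nchars = 2L, eos = NULL)
  w16(42L)
  w32(ifd_offset)
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")  # row-major
  entry <- function(tag, type, count, value) { w16(tag); w16(type); w32(count); w32(value) }
  w16(10L)  # entry count
  entry(256L, 4L, 1L, nc)           # ImageWidth
  entry(257L, 4L, 1L, nr)           # ImageLength
  entry(258L, 3L, 1L, 32L)          # BitsPerSample
  entry(259L, 3L, 1L, 1L)           # Compression: none
  entry(262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
  entry(273L, 4L, 1L, 8L)           # StripOffsets
  entry(277L, 3L, 1L, 1L)           # SamplesPerPixel
  entry(278L, 4L, 1L, nr)           # RowsPerStrip
  entry(279L, 4L, 1L, data_bytes)   # StripByteCounts
  entry(339L, 3L, 1L, 3L)           # SampleFormat: IEEE float
  w32(0L)                           # no next IFD
}

#' Write a foreground mask to disk
#'
#' Masks are written as a 0/1 text matrix or a float TIFF of 0/1 values.
#' @param mask a `foreground_mask` or logical matrix.
#' @param path output file path.
#' @param format `"auto"`, `"tiff"` or `"text"`.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path, format = c("auto", "tiff", "text")) {
  m <- as_mask_matrix(mask, NULL)
  write_height_image(height_image(m * 1.0), path, format = match.arg(format))
}

#' Read a foreground mask written by [write_mask()]
#' @param path file path.
#' @param format `"auto"`, `"tiff"` or `"text"`.
#' @return A `foreground_mask` (all components labelled `"convex"`).
#' @export
read_mask <- function(path, format = c("auto", "tiff", "text")) {
  img <- read_height_image(path, format = match.arg(format))
  foreground_mask(img$heights > 0.5)
}

#' Export contours as a CSV point list
#'
#' One row per contour vertex with columns `component`, `row`, `col`
#' (subpixel, 1-based).
#' @param contours a list of `afm_contour` objects.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- lapply(seq_along(contours), function(i) {
    p <- contours[[i]]$points
    data.frame(component = i, row = p[, 1L], col = p[, 2L])
  })
  df <- if (length(rows) > 0L) do.call(rbind, rows)
        else data.frame(component = integer(), row = numeric(), col = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
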