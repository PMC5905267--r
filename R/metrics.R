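# Morphometry and evaluation: cross-sections, pit depth, residual
# statistics against ground truth, mask agreement, and the two-pass
# segment -> flatten -> segment pipeline.

#' Extract a cross-section profile
#'
#' @param img a `height_image` or numeric matrix.
#' @param index row (for `axis = "row"`) or column index of the slice.
#' @param axis `"row"` (profile runs along the columns of that row) or
#'   `"col"`.
#' @param range optional length-2 integer sub-range along the profile.
#' @return An `afm_profile`: list with `positions_px`, `positions_nm`,
#'   `heights`, `source`.
#' @export
cross_section <- function(img, index, axis = c("row", "col"), range = NULL) {
  img <- as_height_image(img)
  axis <- match.arg(axis)
  d <- dim(img$heights)
  n_along <- if (axis == "row") d[2L] else d[1L]
  n_across <- if (axis == "row") d[1L] else d[2L]
  if (index < 1L || index > n_across)
    stop(sprintf("%s index %d out of range [1, %d]", axis, index, n_across),
         call. = FALSE)
  if (is.null(range)) range <- c(1L, n_along)
  if (range[1L] < 1L || range[2L] > n_along || range[1L] >= range[2L])
    stop("invalid profile range", call. = FALSE)
  pos <- seq.int(range[1L], range[2L])
  hts <- if (axis == "row") img$heights[index, pos] else img$heights[pos, index]
  structure(list(positions_px = pos,
                 positions_nm = (pos - 1) * img$pixel_size_nm,
                 heights = as.numeric(hts),
                 source = list(axis = axis, index = index, range = range)),
            class = "afm_profile")
}

#' @export
print.afm_profile <- function(x, ...) {
  cat(sprintf("<afm_profile> %s %d, %d samples, height range [%.4g, %.4g] nm\n",
              x$source$axis, x$source$index, length(x$heights),
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Feature depth of a cross-section
#'
#' The vertical distance between the highest and the lowest point of the
#' profile -- the standard depth read-out for a calibration-grating pit.
#' On a tilted (unflattened) profile this overestimates the true depth,
#' which is why flattening precedes morphometry.
#'
#' @param profile an `afm_profile` or numeric vector of heights.
#' @return Depth in nm (`max - min`).
#' @export
feature_depth <- function(profile) {
  h <- if (inherits(profile, "afm_profile")) profile$heights else as.numeric(profile)
  if (length(h) < 2L) stop("profile needs at least 2 samples", call. = FALSE)
  max(h) - min(h)
}

#' Plateau-to-floor depth (alternative metric)
#'
#' Median of the upper height cluster minus median of the lower cluster,
#' split at the profile midrange. More robust to single-pixel outliers
#' than the max-minus-min definition but not the standard read-out.
#'
#' @inheritParams feature_depth
#' @return Depth in nm.
#' @export
feature_depth_median <- function(profile) {
  h <- if (inherits(profile, "afm_profile")) profile$heights else as.numeric(profile)
  mid <- (max(h) + min(h)) / 2
  stats::median(h[h >= mid]) - stats::median(h[h < mid])
}

#' Residual statistics of a background estimate
#'
#' Statistics of `background_est - truth_background` restricted to
#' background (unmasked) pixels, after removing the common mean offset:
#' polynomial subtraction is defined only up to the constant absorbed into
#' the background model.
#'
#' @param result a `flatten_result`.
#' @param truth_background a `height_image` or matrix of the true background.
#' @param mask a `foreground_mask`, logical matrix, or `NULL` (all pixels
#'   are background).
#' @return List with `rms`, `max_abs`, `mean_offset` (the removed offset),
#'   `n_background`.
#' @export
residual_stats <- function(result, truth_background, mask = NULL) {
  est <- result$background_est$heights
  truth <- as_height_image(truth_background)$heights
  if (!identical(dim(est), dim(truth)))
    stop("truth background shape does not match the result", call. = FALSE)
  bg <- background_matrix(mask, dim(est))
  d <- (est - truth)[bg]
  if (length(d) == 0L) stop("no background pixels", call. = FALSE)
  mu <- mean(d)
  d <- d - mu
  list(rms = sqrt(mean(d^2)), max_abs = max(abs(d)), mean_offset = mu,
       n_background = length(d))
}

#' Intersection-over-union of two masks
#'
#' @param a,b `foreground_mask` objects or logical matrices of equal shape.
#' @return IoU in `[0, 1]`; defined as 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  ma <- as_mask_matrix(a, NULL)
  mb <- as_mask_matrix(b, NULL)
  if (!identical(dim(ma), dim(mb))) stop("mask shapes differ", call. = FALSE)
  u <- sum(ma | mb)
  if (u == 0L) return(1)
  sum(ma & mb) / u
}

#' Two-pass segmentation with intermediate flattening
#'
#' Pass 1 segments the raw image; the detected features become exclusion
#' masks for flattening; pass 2 segments the flattened image. Flattening
#' removes the background trend that causes over- and under-segmentation
#' on raw images, so the second pass is at least as accurate as the first.
#'
#' @param img a `height_image`.
#' @param seg named list of [segment_features()] arguments (e.g.
#'   `window_px`, `offset_nm`, `min_area_px`, `params`, `polarity`).
#' @param method,order,window,stride,axis flattening settings, see
#'   [flatten_image()].
#' @param dilate_px dilation of the pass-1 mask before flattening.
#' @param max_mask_frac pass-1 components larger than this fraction of the
#'   image are ignored when flattening: a "feature" covering a sizeable
#'   part of the scan is almost surely mis-segmented background, and
#'   excluding it would starve the fits of background pixels. Components
#'   confined entirely to the border band (half the threshold window, where
#'   edge-replicated local means are biased) are ignored for the same
#'   reason.
#' @return List with `mask` (pass 2), `flatten` (the `flatten_result`),
#'   `mask_pass1`.
#' @export
two_pass_segment <- function(img, seg = list(), method = "mef_line",
                             order = 3L, window = 32L, stride = 1L,
                             axis = "fast", dilate_px = 2L,
                             max_mask_frac = 0.1) {
  img <- as_height_image(img)
  m1 <- do.call(segment_features, c(list(img = img), seg))
  use <- m1$included
  ncomp <- max(m1$components)
  if (ncomp > 0L) {
    d <- dim(use)
    band <- (if (is.null(seg$window_px)) 31L else seg$window_px) %/% 2L
    interior <- matrix(FALSE, d[1L], d[2L])
    if (d[1L] > 2L * band && d[2L] > 2L * band)
      interior[(band + 1L):(d[1L] - band), (band + 1L):(d[2L] - band)] <- TRUE
    areas <- tabulate(m1$components[m1$components > 0L], nbins = ncomp)
    for (k in seq_len(ncomp)) {
      sel <- m1$components == k
      if (areas[k] > max_mask_frac * length(use) || !any(sel & interior))
        use[sel] <- FALSE
    }
  }
  fmask <- if (sum(use) > 0L) mask_dilate(foreground_mask(use), dilate_px)
           else NULL
  fr <- flatten_image(img, fmask, method = method, order = order,
                      window = window, stride = stride, axis = axis)
  m2 <- do.call(segment_features, c(list(img = fr$flattened), seg))
  list(mask = m2, flatten = fr, mask_pass1 = m1)
}
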