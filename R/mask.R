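#' Foreground exclusion mask
#'
#' A boolean grid marking the pixels excluded from background fitting,
#' together with an 8-connected component labelling and a per-component
#' polarity (`"convex"` for protrusions such as nanobubbles, `"concave"`
#' for pits, detected on the complement image).
#'
#' @param included logical matrix, `TRUE` = foreground (excluded from fits).
#' @param polarity character vector, one of `"convex"`/`"concave"` per
#'   component, recycled if length 1; defaults to `"convex"`.
#' @return A `foreground_mask`: list with `included` (logical matrix),
#'   `components` (integer matrix, 0 = background), `polarity` (character,
#'   one entry per component).
#' @export
foreground_mask <- function(included, polarity = NULL) {
  if (!is.matrix(included) || !is.logical(included))
    stop("`included` must be a logical matrix", call. = FALSE)
  comp <- label_components(included)
  ncomp <- max(comp)
  if (is.null(polarity)) polarity <- "convex"
  polarity <- rep_len(as.character(polarity), ncomp)
  if (ncomp > 0L && !all(polarity %in% c("convex", "concave")))
    stop("polarity must be 'convex' or 'concave'", call. = FALSE)
  structure(list(included = included, components = comp, polarity = polarity),
            class = "foreground_mask")
}

#' @export
print.foreground_mask <- function(x, ...) {
  cat(sprintf("<foreground_mask> %d x %d px, %d component(s), %d foreground px\n",
              nrow(x$included), ncol(x$included), max(x$components),
              sum(x$included)))
  if (max(x$components) > 0L)
    cat("  polarity:", paste(x$polarity, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.foreground_mask <- function(x) dim(x$included)

# resolve NULL / logical matrix / foreground_mask to a logical matrix of
# foreground (included) pixels
as_mask_matrix <- function(mask, dims = NULL) {
  m <- if (inherits(mask, "foreground_mask")) mask$included
       else if (is.logical(mask) && is.matrix(mask)) mask
       else if (is.null(mask) && !is.null(dims)) matrix(FALSE, dims[1L], dims[2L])
       else stop("mask must be a foreground_mask, a logical matrix, or NULL",
                 call. = FALSE)
  if (!is.null(dims) && !identical(dim(m), as.integer(dims)))
    stop("mask shape does not match the image", call. = FALSE)
  m
}

#' Label 8-connected components of a binary mask
#'
#' Run-based two-pass labelling with union-find; two pixels are connected
#' if they touch by edge or corner.
#'
#' @param mask logical matrix.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in raster order of first appearance.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  run_label <- vector("list", nr)  # per row: matrix(start, end, label)
  prev <- NULL
  for (r in seq_len(nr)) {
    x <- mask[r, ]
    if (!any(x)) { prev <- NULL; next }
    d <- diff(c(FALSE, x, FALSE))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    labs <- integer(length(starts))
    for (k in seq_along(starts)) {
      lab <- 0L
      if (!is.null(prev)) {
        # 8-connectivity: previous-row run overlaps [start-1, end+1]
        ov <- which(prev[, 1L] <= ends[k] + 1L & prev[, 2L] >= starts[k] - 1L)
        for (o in ov) {
          root <- find(prev[o, 3L])
          if (lab == 0L) lab <- root
          else if (root != lab) { parent[max(root, lab)] <- min(root, lab)
                                  lab <- min(root, lab) }
        }
      }
      if (lab == 0L) { parent <- c(parent, length(parent) + 1L)
                       lab <- length(parent) }
      labs[k] <- lab
    }
    run_label[[r]] <- cbind(starts, ends, labs)
    prev <- run_label[[r]]
  }
  if (length(parent) == 0L) return(out)
  roots <- vapply(seq_along(parent), find, integer(1L))
  # renumber components in raster order of first appearance
  remap <- integer(length(parent)); nxt <- 0L
  for (r in seq_len(nr)) {
    rl <- run_label[[r]]
    if (is.null(rl)) next
    for (k in seq_len(nrow(rl))) {
      root <- roots[rl[k, 3L]]
      if (remap[root] == 0L) { nxt <- nxt + 1L; remap[root] <- nxt }
      out[r, rl[k, 1L]:rl[k, 2L]] <- remap[root]
    }
  }
  out
}

#' Dilate a foreground mask
#'
#' Grows the foreground by `px` pixels with a square structuring element.
#' Feature shoulders just outside a detected contour bias background fits;
#' a 1-2 px dilation before flattening removes that bias.
#'
#' @param mask a `foreground_mask` or logical matrix.
#' @param px dilation radius in pixels (0 returns the mask unchanged).
#' @return A `foreground_mask`.
#' @export
mask_dilate <- function(mask, px = 1L) {
  inc <- as_mask_matrix(mask, NULL)
  pol <- if (inherits(mask, "foreground_mask")) mask$polarity else NULL
  if (px > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(px) + 1L, shape = "box")
    inc <- EBImage::dilate(inc * 1, brush) > 0.5
  }
  fm <- foreground_mask(inc)
  # dilation can merge components; relabel polarity by majority vote of the
  # original labels where available
  if (!is.null(pol) && max(fm$components) > 0L && length(pol) > 0L) {
    oldc <- if (inherits(mask, "foreground_mask")) mask$components else NULL
    if (!is.null(oldc)) {
      newpol <- vapply(seq_len(max(fm$components)), function(k) {
        old_ids <- oldc[fm$components == k & oldc > 0L]
        if (length(old_ids) == 0L) return("convex")
        tab <- table(pol[old_ids])
        names(tab)[which.max(tab)]
      }, character(1L))
      fm$polarity <- newpol
    }
  }
  fm
}
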