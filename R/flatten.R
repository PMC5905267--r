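# Background estimation and subtraction. All methods share one contract:
# estimate a per-pixel baseline from background (unmasked) pixels only,
# evaluate it everywhere -- including under foreground features -- and
# subtract it from the whole image.

new_flatten_result <- function(img, baseline, method, params) {
  flattened <- img$heights - baseline
  # background_est is defined as input - flattened so the decomposition is
  # exact by construction
  structure(list(flattened = set_heights(img, flattened),
                 background_est = set_heights(img, img$heights - flattened),
                 method = method, params = params),
            class = "flatten_result")
}

#' @export
print.flatten_result <- function(x, ...) {
  d <- dim(x$flattened)
  cat(sprintf("<flatten_result> method %s, %d x %d px\n", x$method, d[1L], d[2L]))
  cat(sprintf("  flattened range: [%.4g, %.4g] nm\n",
              min(x$flattened$heights), max(x$flattened$heights)))
  fb <- x$params$fallback_lines
  if (!is.null(fb) && fb > 0L)
    cat(sprintf("  %d line(s) baseline-interpolated (too few background points)\n", fb))
  invisible(x)
}

# orient the image so that fitting lines are matrix rows; returns the
# matrix, the mask in the same orientation, and whether we transposed
orient_lines <- function(img, mask, axis) {
  m <- img$heights
  inc <- !background_matrix(mask, dim(m))  # foreground indicator
  rows_are_lines <- (img$fast_axis == "cols") == (axis == "fast")
  if (!rows_are_lines) { m <- t(m); inc <- t(inc) }
  list(m = m, fg = inc, transposed = !rows_are_lines)
}

#' Line-by-line polynomial flattening (direct or mask-exclusion)
#'
#' Fits each scan line with an order-`order` polynomial over its background
#' samples (all samples when `mask` is `NULL`, reproducing direct
#' flattening) and subtracts the full fitted curve from the whole line,
#' foreground included. Lines with fewer than `order + 2` background points
#' get their baseline linearly interpolated per pixel from the nearest
#' valid lines.
#'
#' @param img a `height_image` or numeric matrix.
#' @param mask a `foreground_mask`, logical matrix (TRUE = excluded
#'   foreground) or `NULL` for direct flattening.
#' @param order polynomial order (default 3).
#' @param axis `"fast"` (fit along scan lines, the default -- drift is
#'   lowest within a line) or `"slow"`.
#' @return A `flatten_result` with elements `flattened`, `background_est`
#'   (both `height_image`), `method`, `params`.
#' @examples
#' sc <- add_features(make_background(c(64, 64), background_spec(tilt = c(0.1, 0.2))),
#'                    list(cap_feature(c(32, 32), 10, 15)))
#' fr <- flatten_lines(sc$image, sc$truth_mask)
#' max(abs(fr$flattened$heights - sc$truth_relief$heights))
#' @export
flatten_lines <- function(img, mask = NULL, order = 3L, axis = c("fast", "slow")) {
  img <- as_height_image(img)
  axis <- match.arg(axis)
  check_fit_size(img)
  o <- orient_lines(img, mask, axis)
  m <- o$m; fg <- o$fg
  nr <- nrow(m); nc <- ncol(m)
  baseline <- matrix(NA_real_, nr, nc)
  valid <- logical(nr)
  full_order <- logical(nr)
  X_full <- vander_1d(norm_coord(seq_len(nc), nc), order)
  for (r in seq_len(nr)) {
    inc <- !fg[r, ]
    k <- sum(inc)
    if (k == 0L) next
    # A polynomial fitted to points clustered at one end of the line
    # extrapolates wildly across the rest, so the full order is only used
    # when the background spans most of the line; otherwise the order is
    # stepped down (linear still captures plane tilt and the row's drift
    # offset, a constant at least the offset). Only rows with no
    # background at all fall through to cross-row interpolation.
    span <- max(which(inc)) - min(which(inc)) + 1L
    if (k < order + 2L || span < nc / 2) next
    coef <- qr.coef(qr(X_full[inc, , drop = FALSE]), m[r, inc])
    baseline[r, ] <- drop(X_full %*% coef)
    valid[r] <- TRUE
    full_order[r] <- TRUE
  }
  nfall <- sum(!full_order)
  if (any(!valid)) {
    if (!any(valid))
      stop("no scan line has enough background points to fit", call. = FALSE)
    baseline <- interpolate_invalid_rows(baseline, valid)
    # re-anchor interpolated rows on their own background samples so a
    # per-row drift offset survives even when the row is nearly all
    # foreground
    for (r in which(!valid)) {
      inc <- !fg[r, ]
      if (any(inc))
        baseline[r, ] <- baseline[r, ] + mean(m[r, inc] - baseline[r, inc])
    }
  }
  if (o$transposed) baseline <- t(baseline)
  method <- if (is.null(mask)) "direct_line" else "mef_line"
  new_flatten_result(img, baseline, method,
                     list(order = order, axis = axis, fallback_lines = nfall))
}

#' Whole-image polynomial surface flattening (mask-exclusion)
#'
#' Fits one total-degree-`order` polynomial surface to the background
#' pixels and subtracts it everywhere. A single low-order surface cannot
#' follow per-scan-line drift; use [flatten_lines()] or the sliding-window
#' variants for such images.
#'
#' @inheritParams flatten_lines
#' @return A `flatten_result`.
#' @export
flatten_surface <- function(img, mask = NULL, order = 3L) {
  img <- as_height_image(img)
  check_fit_size(img)
  model <- fit_poly_surface(img, include = background_matrix(mask, dim(img$heights)),
                            order = order)
  new_flatten_result(img, predict(model), "mef_surface", list(order = order))
}

# Baselines for background-starved lines: interior rows are linearly
# interpolated between the nearest valid rows; rows beyond the first/last
# valid row are extrapolated from a least-squares line through the nearest
# (up to 8) valid rows, which follows a tilting background where constant
# extension would leave a ramp remnant.
interpolate_invalid_rows <- function(baseline, valid) {
  vi <- which(valid)
  bad <- which(!valid)
  interior <- bad[bad > vi[1L] & bad < vi[length(vi)]]
  if (length(interior) > 0L)
    for (ccol in seq_len(ncol(baseline)))
      baseline[interior, ccol] <- stats::approx(vi, baseline[vi, ccol],
                                                xout = interior)$y
  extrap <- function(rows_near, rows_out) {
    if (length(rows_near) == 1L)
      return(baseline[rep(rows_near, length(rows_out)), , drop = FALSE])
    x <- rows_near - mean(rows_near)
    sl <- crossprod(x, baseline[rows_near, , drop = FALSE]) / sum(x * x)
    mu <- colMeans(baseline[rows_near, , drop = FALSE])
    outer(rows_out - mean(rows_near), drop(sl)) + rep(mu, each = length(rows_out))
  }
  lo <- bad[bad < vi[1L]]
  if (length(lo) > 0L)
    baseline[lo, ] <- extrap(utils::head(vi, 8L), lo)
  hi <- bad[bad > vi[length(vi)]]
  if (length(hi) > 0L)
    baseline[hi, ] <- extrap(utils::tail(vi, 8L), hi)
  baseline
}

# windows anchored fully inside [1, n]; the final anchor is always
# included so every pixel is covered even when stride > 1
window_anchors <- function(n, w, stride) {
  last <- n - w + 1L
  a <- seq.int(1L, last, by = stride)
  if (a[length(a)] != last) a <- c(a, last)
  a
}

# fill positions never covered by a valid window by linear interpolation
# from covered positions (constant extrapolation at the ends)
fill_uncovered_1d <- function(base, cnt) {
  if (all(cnt > 0)) return(base / cnt)
  cov <- which(cnt > 0)
  if (length(cov) == 0L) stop("no window had enough background points",
                              call. = FALSE)
  out <- base
  out[cov] <- base[cov] / cnt[cov]
  out[-cov] <- stats::approx(cov, out[cov], xout = which(cnt == 0), rule = 2)$y
  out
}

#' Sliding-window polynomial curve flattening (SWCF)
#'
#' For each scan line, a window of `window` pixels slides along the line
#' (stride 1 by default); at each position an order-`order` polynomial is
#' fitted to the in-window background samples and evaluated at every
#' in-window pixel. Each pixel's baseline is the average of all such
#' evaluations, which lets the baseline follow background trends no single
#' global polynomial can represent. Windows with fewer than `order + 2`
#' background samples are skipped; pixels covered by no valid window are
#' interpolated from covered neighbours.
#'
#' @inheritParams flatten_lines
#' @param window window width in pixels (>= `order + 2`).
#' @param stride anchor step in pixels (default 1; the final anchor is
#'   always included so every pixel is covered).
#' @return A `flatten_result`.
#' @export
swcf <- function(img, mask = NULL, window = 32L, order = 3L,
                 axis = c("fast", "slow"), stride = 1L) {
  img <- as_height_image(img)
  axis <- match.arg(axis)
  check_fit_size(img)
  w <- as.integer(window[1L])
  if (w < order + 2L) stop("window must be >= order + 2", call. = FALSE)
  o <- orient_lines(img, mask, axis)
  m <- o$m; fg <- o$fg
  nr <- nrow(m); nc <- ncol(m)
  if (w > nc) stop("window wider than the scan line", call. = FALSE)
  anchors <- window_anchors(nc, w, as.integer(stride))
  na <- length(anchors)
  X <- vander_1d(norm_coord(seq_len(w), w), order)
  P <- solve(crossprod(X), t(X))        # shared projector for clean windows
  H <- X %*% P                          # w x w hat matrix
  baseline <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    y <- m[r, ]; f <- fg[r, ]
    acc <- numeric(nc); cnt <- numeric(nc)
    # classify windows: clean = no foreground inside
    fcum <- cumsum(c(0L, f))
    nfg <- fcum[anchors + w] - fcum[anchors]
    clean <- which(nfg == 0L)
    dirty <- which(nfg > 0L)
    if (length(clean) > 0L) {
      Y <- matrix(y[outer(0:(w - 1L), anchors[clean], `+`)], w)
      E <- H %*% Y
      for (k in seq_len(w)) {
        ind <- anchors[clean] + k - 1L
        acc[ind] <- acc[ind] + E[k, ]
        cnt[ind] <- cnt[ind] + 1
      }
    }
    for (j in dirty) {
      a <- anchors[j]
      sel <- a:(a + w - 1L)
      inw <- !f[sel]
      if (sum(inw) < order + 2L) next
      qx <- qr(X[inw, , drop = FALSE])
      if (qx$rank < ncol(X)) next
      coef <- qr.coef(qx, y[sel][inw])
      acc[sel] <- acc[sel] + drop(X %*% coef)
      cnt[sel] <- cnt[sel] + 1
    }
    baseline[r, ] <- if (any(cnt > 0)) fill_uncovered_1d(acc, cnt)
                     else NA_real_
  }
  bad <- is.na(baseline[, 1L])
  if (any(bad)) {
    if (all(bad)) stop("no window had enough background points", call. = FALSE)
    baseline <- interpolate_invalid_rows(baseline, !bad)
  }
  if (o$transposed) baseline <- t(baseline)
  new_flatten_result(img, baseline, "swcf",
                     list(order = order, window = w, stride = as.integer(stride),
                          axis = axis))
}

#' Sliding-window polynomial surface flattening (SWSF)
#'
#' Two-dimensional analogue of [swcf()]: a `window[1] x window[2]` window
#' slides over the image along both axes; per position a total-degree
#' `order` polynomial surface is fitted to the in-window background pixels
#' and evaluated over the whole window; the per-pixel baseline is the
#' average of all evaluations.
#'
#' @inheritParams swcf
#' @param window length-1 or length-2 integer window size (rows, cols).
#' @return A `flatten_result`.
#' @export
swsf <- function(img, mask = NULL, window = c(32L, 32L), order = 3L,
                 stride = 1L) {
  img <- as_height_image(img)
  check_fit_size(img)
  if (length(window) == 1L) window <- c(window, window)
  wh <- as.integer(window[1L]); ww <- as.integer(window[2L])
  m <- img$heights
  fg <- !background_matrix(mask, dim(m))
  nr <- nrow(m); nc <- ncol(m)
  if (wh > nr || ww > nc) stop("window larger than the image", call. = FALSE)
  ex <- monomials_2d(order)
  kmin <- nrow(ex) + 1L
  if (wh * ww < kmin) stop("window too small for the surface basis", call. = FALSE)
  ar <- window_anchors(nr, wh, as.integer(stride))
  ac <- window_anchors(nc, ww, as.integer(stride))
  u <- norm_coord(seq_len(wh), wh); v <- norm_coord(seq_len(ww), ww)
  U <- rep(u, times = ww); V <- rep(v, each = wh)   # column-major window order
  X <- vander_2d(U, V, order)
  P <- solve(crossprod(X), t(X))
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  fgc <- rbind(0, apply(fg, 2L, cumsum))           # column-wise cumsum, padded
  # count of foreground pixels in each window via 2-D summed-area table
  sat <- cbind(0, t(apply(fgc, 1L, cumsum)))
  win_fg <- function(r, c) sat[r + wh, c + ww] - sat[r, c + ww] -
                           sat[r + wh, c] + sat[r, c]
  grid <- expand.grid(r = ar, c = ac)
  nfg <- mapply(win_fg, grid$r, grid$c)
  clean <- which(nfg == 0L)
  dirty <- which(nfg > 0L)
  chunk <- max(1L, floor(2e6 / (wh * ww)))
  for (s in split(clean, ceiling(seq_along(clean) / chunk))) {
    Y <- vapply(s, function(g) as.numeric(m[grid$r[g]:(grid$r[g] + wh - 1L),
                                            grid$c[g]:(grid$c[g] + ww - 1L)]),
                numeric(wh * ww))
    E <- X %*% (P %*% Y)
    for (i in seq_along(s)) {
      g <- s[i]
      rs <- grid$r[g]:(grid$r[g] + wh - 1L)
      cs <- grid$c[g]:(grid$c[g] + ww - 1L)
      acc[rs, cs] <- acc[rs, cs] + E[, i]
      cnt[rs, cs] <- cnt[rs, cs] + 1
    }
  }
  for (g in dirty) {
    rs <- grid$r[g]:(grid$r[g] + wh - 1L)
    cs <- grid$c[g]:(grid$c[g] + ww - 1L)
    inw <- !fg[rs, cs]
    if (sum(inw) < kmin) next
    qx <- qr(X[inw, , drop = FALSE])
    if (qx$rank < ncol(X)) next
    coef <- qr.coef(qx, m[rs, cs][inw])
    acc[rs, cs] <- acc[rs, cs] + matrix(drop(X %*% coef), wh, ww)
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  if (any(cnt == 0)) {
    # interpolate uncovered pixels row-wise, then column-wise for any rows
    # with no coverage at all
    for (r in seq_len(nr)) {
      if (all(cnt[r, ] > 0)) { acc[r, ] <- acc[r, ] / cnt[r, ]; next }
      cov <- which(cnt[r, ] > 0)
      if (length(cov) == 0L) next
      acc[r, ] <- fill_uncovered_1d(acc[r, ], cnt[r, ])
      cnt[r, ] <- 1
    }
    for (ccol in seq_len(nc)) {
      bad <- cnt[, ccol] == 0
      if (!any(bad)) next
      cov <- which(!bad)
      if (length(cov) == 0L)
        stop("no window had enough background pixels", call. = FALSE)
      acc[bad, ccol] <- stats::approx(cov, acc[cov, ccol],
                                      xout = which(bad), rule = 2)$y
    }
    baseline <- acc
  } else baseline <- acc / cnt
  new_flatten_result(img, baseline, "swsf",
                     list(order = order, window = c(wh, ww),
                          stride = as.integer(stride)))
}

#' Run a flattening method by name
#'
#' Dispatch helper used by the command-line front end and the two-pass
#' pipeline.
#'
#' @param img a `height_image`.
#' @param mask mask argument passed through (may be `NULL`).
#' @param method one of `"direct_line"`, `"mef_line"`, `"mef_surface"`,
#'   `"swcf"`, `"swsf"`.
#' @param order polynomial order.
#' @param window window size for the sliding-window methods.
#' @param stride anchor stride for the sliding-window methods.
#' @param axis fitting direction for the line-based methods.
#' @return A `flatten_result`.
#' @export
flatten_image <- function(img, mask = NULL,
                          method = c("mef_line", "direct_line", "mef_surface",
                                     "swcf", "swsf"),
                          order = 3L, window = 32L, stride = 1L, axis = "fast") {
  method <- match.arg(method)
  switch(method,
         direct_line = flatten_lines(img, NULL, order = order, axis = axis),
         mef_line = flatten_lines(img, mask, order = order, axis = axis),
         mef_surface = flatten_surface(img, mask, order = order),
         swcf = swcf(img, mask, window = window[1L], order = order,
                     axis = axis, stride = stride),
         swsf = swsf(img, mask, window = window, order = order, stride = stride))
}
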