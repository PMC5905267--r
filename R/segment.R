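# Step 1 of the two-step flattening scheme: automated extraction of
# foreground features as exclusion masks. Adaptive local-mean thresholding
# gives an under-estimating initial contour; a greedy active contour
# ("contour expansion") then evolves outward, driven by the gradient field
# of the image, until it converges on the actual feature boundary.
# Concave features are detected by running the same machinery on the
# complement image.

#' Active-contour (contour expansion) parameters
#'
#' The internal-energy coefficients `alpha` (continuity) and `beta`
#' (smoothness) restrain the contour: large values lead to less-expanded
#' contours and under-estimated boundaries, small values let the contour
#' follow the gradient field closely and over-estimate. `gamma` weights the
#' attraction to high gradient magnitude and `pressure` the outward
#' balloon force that drives expansion across flat flanks.
#'
#' @param alpha continuity weight (>= 0).
#' @param beta curvature (smoothness) weight (>= 0).
#' @param gamma image-force weight (> 0).
#' @param pressure outward expansion weight (>= 0).
#' @param gradient_sigma_px Gaussian smoothing sigma (px) applied before
#'   the gradient field is computed; raw pixel gradients are
#'   noise-dominated on AFM data.
#' @param neighborhood odd integer >= 3, side of the candidate-move grid.
#' @param max_iter iteration cap.
#' @param move_tol convergence: stop when the fraction of points that
#'   moved falls below this.
#' @param resample_every resample the contour to uniform spacing every
#'   this many iterations.
#' @param point_spacing_px target spacing between contour points (px).
#' @return A `snake_params` list.
#' @export
snake_params <- function(alpha = 0.4, beta = 0.4, gamma = 1.2, pressure = 0.35,
                         gradient_sigma_px = 1, neighborhood = 3L,
                         max_iter = 200L, move_tol = 0.05,
                         resample_every = 5L, point_spacing_px = 2) {
  stopifnot(alpha >= 0, beta >= 0, gamma > 0, pressure >= 0,
            gradient_sigma_px > 0, neighborhood >= 3L,
            neighborhood %% 2L == 1L, max_iter >= 1L,
            move_tol > 0, move_tol <= 1, resample_every >= 1L,
            point_spacing_px > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, pressure = pressure,
                 gradient_sigma_px = gradient_sigma_px,
                 neighborhood = as.integer(neighborhood),
                 max_iter = as.integer(max_iter), move_tol = move_tol,
                 resample_every = as.integer(resample_every),
                 point_spacing_px = point_spacing_px),
            class = "snake_params")
}

new_contour <- function(points, converged = FALSE, iterations = 0L) {
  structure(list(points = points, converged = converged,
                 iterations_used = as.integer(iterations)),
            class = "afm_contour")
}

#' @export
print.afm_contour <- function(x, ...) {
  cat(sprintf("<afm_contour> %d points, %s after %d iteration(s)\n",
              nrow(x$points),
              if (x$converged) "converged" else "not converged",
              x$iterations_used))
  invisible(x)
}

#' Adaptive local-mean thresholding
#'
#' A pixel is foreground iff its height exceeds the mean over the
#' `window_px` x `window_px` neighbourhood (edge-replicated) by more than
#' `offset_nm`. The local mean tracks smooth background trends, so the
#' threshold adapts to tilt and bow; the offset sets the minimum height a
#' feature must rise above its local surroundings.
#'
#' @param img a `height_image` or numeric matrix.
#' @param window_px odd window side, >= 3 and smaller than both image
#'   dimensions.
#' @param offset_nm threshold offset in nm.
#' @return Logical matrix (`TRUE` = foreground candidate).
#' @export
adaptive_threshold <- function(img, window_px = 31L, offset_nm = 1) {
  img <- as_height_image(img)
  m <- img$heights
  w <- as.integer(window_px)
  if (w < 3L || w %% 2L == 0L) stop("window_px must be odd and >= 3", call. = FALSE)
  if (w >= nrow(m) || w >= ncol(m))
    stop("window_px must be smaller than both image dimensions", call. = FALSE)
  m > local_mean(m, w) + offset_nm
}

# box mean with edge replication, separable running sums
local_mean <- function(m, w) {
  h <- (w - 1L) %/% 2L
  pad_rows <- c(rep(1L, h), seq_len(nrow(m)), rep(nrow(m), h))
  pad_cols <- c(rep(1L, h), seq_len(ncol(m)), rep(ncol(m), h))
  p <- m[pad_rows, pad_cols, drop = FALSE]
  cs <- rbind(0, apply(p, 2L, cumsum))
  rowsum_ <- cs[(w + 1L):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - w), , drop = FALSE]
  cs2 <- cbind(0, t(apply(rowsum_, 1L, cumsum)))
  (cs2[, (w + 1L):ncol(cs2), drop = FALSE] - cs2[, 1:(ncol(cs2) - w), drop = FALSE]) / (w * w)
}

#' Initial contours from a threshold mask
#'
#' Extracts one closed contour per 8-connected component of at least
#' `min_area_px` pixels, traced along the component boundary and resampled
#' to uniform point spacing. These under-estimating contours seed the
#' contour-expansion refinement.
#'
#' @param mask logical matrix (e.g. from [adaptive_threshold()]).
#' @param min_area_px minimum component area in pixels.
#' @param point_spacing_px target contour point spacing.
#' @return List of `afm_contour` objects (possibly empty).
#' @export
initial_contours <- function(mask, min_area_px = 20L, point_spacing_px = 2) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0L) return(list())
  oc <- EBImage::ocontour(lab)
  out <- list()
  for (k in keep) {
    pts <- oc[[k]] + 1  # ocontour is 0-based (row, col)
    if (is.null(pts) || nrow(pts) < 4L) next
    out[[length(out) + 1L]] <- new_contour(resample_closed(pts, point_spacing_px))
  }
  out
}

# resample a closed polygon to uniform arc-length spacing (>= 8 points)
resample_closed <- function(pts, spacing) {
  pts <- as.matrix(pts)
  dup <- c(FALSE, rowSums(abs(diff(pts))) < 1e-9)
  pts <- pts[!dup, , drop = FALSE]
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  L <- sum(seg)
  n_new <- max(8L, as.integer(round(L / spacing)))
  s <- c(0, cumsum(seg))
  t_new <- seq(0, L, length.out = n_new + 1L)[-(n_new + 1L)]
  cbind(stats::approx(s, closed[, 1L], xout = t_new)$y,
        stats::approx(s, closed[, 2L], xout = t_new)$y)
}

polygon_area <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1L)
  abs(sum(pts[, 1L] * pts[j, 2L] - pts[j, 1L] * pts[, 2L])) / 2
}

# Gaussian-smoothed gradient magnitude, central differences with edge
# replication
gradient_magnitude <- function(m, sigma) {
  g <- EBImage::gblur(m, sigma = sigma)
  nr <- nrow(g); nc <- ncol(g)
  gr <- (g[pmin(seq_len(nr) + 1L, nr), ] - g[pmax(seq_len(nr) - 1L, 1L), ]) / 2
  gc <- (g[, pmin(seq_len(nc) + 1L, nc)] - g[, pmax(seq_len(nc) - 1L, 1L)]) / 2
  sqrt(gr^2 + gc^2)
}

interp_bilinear <- function(M, r, c) {
  nr <- nrow(M); nc <- ncol(M)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  M[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    M[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    M[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    M[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Expand a contour to the feature boundary
#'
#' Greedy active-contour iteration. Each point examines the candidate
#' moves in its `neighborhood` x `neighborhood` grid and takes the one
#' minimising
#' \deqn{E = \alpha E_{cont} + \beta E_{curv} - \gamma |\nabla I_\sigma|
#'       - p \, E_{press},}
#' where \eqn{E_{cont}} penalises deviation from the mean point spacing,
#' \eqn{E_{curv}} the discrete curvature, \eqn{|\nabla I_\sigma|} is the
#' smoothed gradient magnitude and \eqn{E_{press}} the outward
#' displacement; each term is min-max normalised over the neighbourhood.
#' The contour is resampled to uniform spacing every `resample_every`
#' iterations and iteration stops when fewer than `move_tol` of the points
#' moved, or at `max_iter`.
#'
#' @param img a `height_image` or numeric matrix.
#' @param contour an `afm_contour` (e.g. from [initial_contours()]).
#' @param params a [snake_params()].
#' @return The evolved `afm_contour` with `converged` and
#'   `iterations_used` set.
#' @export
expand_contour <- function(img, contour, params = snake_params()) {
  img <- as_height_image(img)
  gm <- gradient_magnitude(img$heights, params$gradient_sigma_px)
  expand_contour_impl(gm, dim(img$heights), contour, params)
}

expand_contour_impl <- function(gm, dims, contour, params) {
  pts <- contour$points
  nr <- dims[1L]; nc <- dims[2L]
  h <- (params$neighborhood - 1L) %/% 2L
  offs <- as.matrix(expand.grid(dr = -h:h, dc = -h:h))
  # (0,0) first so that on ties the point stays put
  offs <- offs[order(offs[, 1L]^2 + offs[, 2L]^2, offs[, 1L], offs[, 2L]), ,
               drop = FALSE]
  noff <- nrow(offs)
  eps <- 1e-12
  converged <- FALSE
  it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    n <- nrow(pts)
    prev <- pts[c(n, seq_len(n - 1L)), , drop = FALSE]
    nxt <- pts[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
    dbar <- mean(sqrt(rowSums((pts - prev)^2)))
    ctr <- colMeans(pts)
    outv <- sweep(pts, 2L, ctr)
    outv <- outv / pmax(sqrt(rowSums(outv^2)), eps)
    Ec <- Ek <- Ei <- Ep <- matrix(0, n, noff)
    for (o in seq_len(noff)) {
      cand_r <- pts[, 1L] + offs[o, 1L]
      cand_c <- pts[, 2L] + offs[o, 2L]
      Ec[, o] <- (dbar - sqrt((cand_r - prev[, 1L])^2 + (cand_c - prev[, 2L])^2))^2
      Ek[, o] <- (prev[, 1L] - 2 * cand_r + nxt[, 1L])^2 +
                 (prev[, 2L] - 2 * cand_c + nxt[, 2L])^2
      Ei[, o] <- interp_bilinear(gm, cand_r, cand_c)
      Ep[, o] <- offs[o, 1L] * outv[, 1L] + offs[o, 2L] * outv[, 2L]
    }
    nrm <- function(E) {
      lo <- apply(E, 1L, min); hi <- apply(E, 1L, max)
      (E - lo) / pmax(hi - lo, eps)
    }
    total <- params$alpha * nrm(Ec) + params$beta * nrm(Ek) -
             params$gamma * nrm(Ei) - params$pressure * nrm(Ep)
    choice <- max.col(-total, ties.method = "first")
    pts[, 1L] <- pmin(pmax(pts[, 1L] + offs[choice, 1L], 1.01), nr - 0.01)
    pts[, 2L] <- pmin(pmax(pts[, 2L] + offs[choice, 2L], 1.01), nc - 0.01)
    still <- offs[choice, 1L] == 0 & offs[choice, 2L] == 0
    if (mean(!still) < params$move_tol) { converged <- TRUE; break }
    if (it %% params$resample_every == 0L)
      pts <- resample_closed(pts, params$point_spacing_px)
  }
  pts <- resample_closed(pts, params$point_spacing_px)
  if (nrow(pts) < 8L || polygon_area(pts) < 1)
    stop(structure(class = c("afm_degenerate_contour", "error", "condition"),
                   list(message = "contour degenerated during expansion",
                        call = NULL)))
  new_contour(pts, converged = converged, iterations = it)
}

# even-odd scanline rasterization; boundary (vertex) pixels are included
rasterize_contour <- function(pts, dims) {
  nr <- dims[1L]; nc <- dims[2L]
  out <- matrix(FALSE, nr, nc)
  n <- nrow(pts)
  r1 <- pts[, 1L]; c1 <- pts[, 2L]
  r2 <- pts[c(2:n, 1L), 1L]; c2 <- pts[c(2:n, 1L), 2L]
  for (y in seq_len(nr)) {
    hit <- (r1 <= y) != (r2 <= y)
    if (!any(hit)) next
    t <- (y - r1[hit]) / (r2[hit] - r1[hit])
    xs <- sort(c1[hit] + t * (c2[hit] - c1[hit]))
    k <- 1L
    while (k + 1L <= length(xs)) {
      a <- ceiling(xs[k] - 1e-9); b <- floor(xs[k + 1L] + 1e-9)
      if (b >= a) out[y, max(1L, a):min(nc, b)] <- TRUE
      k <- k + 2L
    }
  }
  vr <- pmin(pmax(round(r1), 1L), nr)
  vc <- pmin(pmax(round(c1), 1L), nc)
  out[cbind(vr, vc)] <- TRUE
  out
}

#' Segment convex and concave foreground features
#'
#' The full first step of the flattening scheme: adaptive thresholding
#' (after 3x3 morphological opening and a minimum-area filter) yields
#' initial contours, contour expansion refines each to the feature
#' boundary, and the final contours are rasterised (even-odd rule,
#' boundary included) into an exclusion mask. Convex features are detected
#' on the image itself and concave features by the identical procedure on
#' [complement_image()]; the returned mask is the union, with per-component
#' polarity labels.
#'
#' @param img a `height_image` or numeric matrix.
#' @param polarity `"both"`, `"convex"` or `"concave"`.
#' @param window_px,offset_nm adaptive-threshold parameters
#'   (see [adaptive_threshold()]).
#' @param min_area_px minimum component area kept after thresholding.
#' @param params a [snake_params()].
#' @param dilate_px dilation applied to the final mask (default 1 px:
#'   feature shoulders just outside the detected contour bias background
#'   fits; set 0 for the undilated contours).
#' @return A `foreground_mask`.
#' @export
segment_features <- function(img, polarity = c("both", "convex", "concave"),
                             window_px = 31L, offset_nm = 1,
                             min_area_px = 20L, params = snake_params(),
                             dilate_px = 1L) {
  img <- as_height_image(img)
  polarity <- match.arg(polarity)
  d <- dim(img$heights)
  conv <- conc <- matrix(FALSE, d[1L], d[2L])
  if (polarity %in% c("both", "convex"))
    conv <- segment_convex(img, window_px, offset_nm, min_area_px, params)
  if (polarity %in% c("both", "concave"))
    conc <- segment_convex(complement_image(img), window_px, offset_nm,
                           min_area_px, params)
  fm <- foreground_mask(conv | conc)
  if (max(fm$components) > 0L)
    fm$polarity <- vapply(seq_len(max(fm$components)), function(k) {
      sel <- fm$components == k
      if (sum(conv[sel]) >= sum(conc[sel])) "convex" else "concave"
    }, character(1L))
  if (dilate_px > 0L) fm <- mask_dilate(fm, dilate_px)
  fm
}

# one convex pass: threshold -> open -> contours -> expand -> rasterize ->
# convexity check
segment_convex <- function(img, window_px, offset_nm, min_area_px, params) {
  m <- img$heights
  thr <- adaptive_threshold(img, window_px, offset_nm)
  thr <- EBImage::opening(thr * 1, EBImage::makeBrush(3L, "box")) > 0.5
  cs <- initial_contours(thr, min_area_px, params$point_spacing_px)
  out <- matrix(FALSE, nrow(m), ncol(m))
  if (length(cs) == 0L) return(out)
  gm <- gradient_magnitude(m, params$gradient_sigma_px)
  for (c0 in cs) {
    cf <- tryCatch(expand_contour_impl(gm, dim(m), c0, params),
                   afm_degenerate_contour = function(e) NULL)
    if (is.null(cf)) next
    out <- out | rasterize_contour(cf$points, dim(m))
  }
  keep_convex_components(out, m, min_area_px)
}

# Drop detected components that are not actually protrusions: the local
# mean under an opposite-polarity feature is depressed, so adaptive
# thresholding also fires on the flat ring around it; such rings enclose
# the (low) feature once rasterized, so their interior mean does not rise
# above the surrounding band. Also re-applies the minimum-area filter to
# the rasterized components.
keep_convex_components <- function(out, m, min_area_px) {
  lab <- label_components(out)
  n <- max(lab)
  if (n == 0L) return(out)
  brush <- EBImage::makeBrush(5L, "box")
  for (k in seq_len(n)) {
    sel <- lab == k
    if (sum(sel) < min_area_px) { out[sel] <- FALSE; next }
    ring <- (EBImage::dilate(sel * 1, brush) > 0.5) & !sel
    if (sum(ring) == 0L) next
    if (mean(m[sel]) <= mean(m[ring])) out[sel] <- FALSE
  }
  out
}
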