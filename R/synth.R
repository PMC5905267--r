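# Synthetic AFM scenes with ground truth. The generator emulates the
# artifact classes seen in real scans -- plane tilt, quadratic/cubic bow,
# low-frequency sinusoids, per-scan-line drift offsets, Gaussian pixel
# noise -- plus spherical-cap protrusions (nanobubbles), pits, and square-pit
# calibration gratings.

#' Background artifact specification
#'
#' @param tilt length-2 numeric `(g_row, g_col)`: plane gradient in nm per
#'   pixel along the slow (row) and fast (column) axes.
#' @param bow named numeric vector of polynomial bow coefficients in
#'   normalized coordinates \eqn{u, v \in [-1, 1]} (row, col). Recognised
#'   names: `u2`, `v2`, `uv`, `u3`, `v3`, `u2v`, `uv2` (nm at coordinate 1).
#' @param sinusoids data frame with columns `amplitude` (nm), `period`
#'   (px, > 4), `phase` (rad) and `axis` (`"row"` or `"col"`: the index the
#'   wave varies along), or `NULL`.
#' @param drift_sd per-scan-line drift: standard deviation (nm) of the
#'   random-walk step between consecutive rows; the offset is constant
#'   within each row, mirroring drift that accumulates along the slow axis.
#' @param noise_sd additive Gaussian pixel noise standard deviation (nm).
#' @return A `background_spec` list.
#' @export
background_spec <- function(tilt = c(0, 0), bow = NULL, sinusoids = NULL,
                            drift_sd = 0, noise_sd = 0) {
  stopifnot(length(tilt) == 2L, all(is.finite(tilt)))
  if (!is.null(bow)) {
    ok <- c("u2", "v2", "uv", "u3", "v3", "u2v", "uv2")
    if (is.null(names(bow)) || !all(names(bow) %in% ok))
      stop("bow coefficients must be named from: ", paste(ok, collapse = ", "),
           call. = FALSE)
    stopifnot(all(is.finite(bow)))
  }
  if (!is.null(sinusoids)) {
    sinusoids <- as.data.frame(sinusoids)
    need <- c("amplitude", "period", "phase", "axis")
    if (!all(need %in% names(sinusoids)))
      stop("sinusoids need columns: ", paste(need, collapse = ", "), call. = FALSE)
    if (any(sinusoids$period <= 4))
      stop("sinusoid periods must exceed 4 px", call. = FALSE)
    if (any(!is.finite(sinusoids$amplitude)))
      stop("sinusoid amplitudes must be finite", call. = FALSE)
    if (!all(sinusoids$axis %in% c("row", "col")))
      stop("sinusoid axis must be 'row' or 'col'", call. = FALSE)
  }
  if (drift_sd < 0 || noise_sd < 0)
    stop("drift_sd and noise_sd must be >= 0", call. = FALSE)
  structure(list(tilt = as.numeric(tilt), bow = bow, sinusoids = sinusoids,
                 drift_sd = drift_sd, noise_sd = noise_sd),
            class = "background_spec")
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic background image
#'
#' Sums the components of a [background_spec()]: plane tilt, bow,
#' sinusoids, per-row random-walk drift and Gaussian noise. Deterministic
#' for a fixed seed.
#'
#' @param shape length-2 integer `(n_rows, n_cols)`.
#' @param spec a [background_spec()].
#' @param seed integer seed for the stochastic components.
#' @param pixel_size_nm pixel size to attach.
#' @return A `height_image`.
#' @export
make_background <- function(shape, spec = background_spec(), seed = 1L,
                            pixel_size_nm = 1) {
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  if (!inherits(spec, "background_spec")) spec <- do.call(background_spec, spec)
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  r <- seq_len(nr) - 1; c <- seq_len(nc) - 1
  m <- outer(spec$tilt[1L] * r, rep(1, nc)) + outer(rep(1, nr), spec$tilt[2L] * c)
  if (!is.null(spec$bow)) {
    u <- norm_coord(seq_len(nr), nr); v <- norm_coord(seq_len(nc), nc)
    terms <- list(u2 = outer(u^2, rep(1, nc)),  v2 = outer(rep(1, nr), v^2),
                  uv = outer(u, v),             u3 = outer(u^3, rep(1, nc)),
                  v3 = outer(rep(1, nr), v^3),  u2v = outer(u^2, v),
                  uv2 = outer(u, v^2))
    for (nm in names(spec$bow)) m <- m + spec$bow[[nm]] * terms[[nm]]
  }
  if (!is.null(spec$sinusoids)) {
    for (k in seq_len(nrow(spec$sinusoids))) {
      s <- spec$sinusoids[k, ]
      if (s$axis == "row") {
        w <- s$amplitude * sin(2 * pi * r / s$period + s$phase)
        m <- m + outer(w, rep(1, nc))
      } else {
        w <- s$amplitude * sin(2 * pi * c / s$period + s$phase)
        m <- m + outer(rep(1, nr), w)
      }
    }
  }
  if (spec$drift_sd > 0 || spec$noise_sd > 0) {
    m <- m + with_seed(seed, {
      drift <- if (spec$drift_sd > 0) cumsum(stats::rnorm(nr, 0, spec$drift_sd))
               else numeric(nr)
      noise <- if (spec$noise_sd > 0) matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
               else matrix(0, nr, nc)
      outer(drift, rep(1, nc)) + noise
    })
  }
  height_image(m, pixel_size_nm = pixel_size_nm)
}

#' Feature specifications
#'
#' `cap_feature()` describes a spherical-cap protrusion (a surface
#' nanobubble); `pit_feature()` the same shape subtracted (a nanopit).
#' The relief is \eqn{z(\rho) = h (1 - \rho^2/r^2) s(\rho)} where
#' \eqn{s} is a raised-cosine shoulder over the outer 10% of the footprint
#' radius; a pure cap has a gradient discontinuity at the rim that would
#' make edge detection unrealistically easy.
#'
#' @param center length-2 numeric `(row, col)` of the apex, 1-based pixels.
#' @param radius footprint radius in pixels (> 2).
#' @param height apex height in nm (> 0) for caps.
#' @param depth pit depth in nm (> 0) for pits.
#' @return A `feature_spec` list.
#' @export
cap_feature <- function(center, radius, height) {
  stopifnot(length(center) == 2L, radius > 2, height > 0)
  structure(list(kind = "cap", center = as.numeric(center),
                 radius = as.numeric(radius), height = as.numeric(height)),
            class = "feature_spec")
}

#' @rdname cap_feature
#' @export
pit_feature <- function(center, radius, depth) {
  stopifnot(length(center) == 2L, radius > 2, depth > 0)
  structure(list(kind = "pit", center = as.numeric(center),
                 radius = as.numeric(radius), depth = as.numeric(depth)),
            class = "feature_spec")
}

# spherical-cap height field with raised-cosine shoulder over the outer
# 10% of the footprint radius
cap_relief <- function(shape, center, radius, height) {
  nr <- shape[1L]; nc <- shape[2L]
  rho <- sqrt(outer((seq_len(nr) - center[1L])^2, rep(1, nc)) +
              outer(rep(1, nr), (seq_len(nc) - center[2L])^2))
  z <- height * pmax(0, 1 - rho^2 / radius^2)
  edge <- 0.9 * radius
  sh <- ifelse(rho <= edge, 1,
               ifelse(rho < radius,
                      0.5 * (1 + cos(pi * (rho - edge) / (radius - edge))), 0))
  z * sh
}

#' Add features to a background image
#'
#' Builds a complete synthetic scene: the relief of each feature is added
#' to (caps) or subtracted from (pits) the background, and the ground-truth
#' mask marks exactly the pixels with nonzero relief.
#'
#' @param bg a `height_image` background (e.g. from [make_background()]).
#' @param features list of [cap_feature()] / [pit_feature()] specs.
#' @param noise image noise already present in `bg`; informational, stored
#'   on the scene (nm).
#' @return An `afm_scene`: list with `image`, `truth_background`,
#'   `truth_relief` (all `height_image`), `truth_mask` (`foreground_mask`),
#'   `features`.
#' @export
add_features <- function(bg, features = list(), noise = 0) {
  bg <- as_height_image(bg)
  d <- dim(bg$heights)
  relief <- matrix(0, d[1L], d[2L])
  inc <- matrix(FALSE, d[1L], d[2L])
  pol <- character(0)
  for (f in features) {
    if (!inherits(f, "feature_spec")) stop("features must be feature_spec objects",
                                           call. = FALSE)
    if (f$center[1L] - f$radius < 1 || f$center[1L] + f$radius > d[1L] ||
        f$center[2L] - f$radius < 1 || f$center[2L] + f$radius > d[2L])
      stop(sprintf("feature at (%g, %g) with radius %g extends outside the image",
                   f$center[1L], f$center[2L], f$radius), call. = FALSE)
    amp <- if (f$kind == "cap") f$height else -f$depth
    z <- cap_relief(d, f$center, f$radius, abs(amp)) * sign(amp)
    relief <- relief + z
    inc <- inc | (z != 0)
    pol <- c(pol, if (f$kind == "cap") "convex" else "concave")
  }
  mask <- foreground_mask(inc)
  # polarity per labelled component from the dominant relief sign
  if (max(mask$components) > 0L)
    mask$polarity <- vapply(seq_len(max(mask$components)), function(k) {
      if (mean(relief[mask$components == k]) >= 0) "convex" else "concave"
    }, character(1L))
  structure(list(image = set_heights(bg, bg$heights + relief),
                 truth_background = bg,
                 truth_relief = set_heights(bg, relief),
                 truth_mask = mask,
                 features = features,
                 noise_sd = noise),
            class = "afm_scene")
}

#' @export
print.afm_scene <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<afm_scene> %d x %d px, %d feature(s), %d foreground px\n",
              d[1L], d[2L], length(x$features), sum(x$truth_mask$included)))
  invisible(x)
}

#' Generate a square-pit calibration-grating scene
#'
#' Square pits of uniform depth on a periodic lattice, emulating a
#' calibration grating, plus an arbitrary background. The ground-truth mask
#' covers the pit interiors.
#'
#' @param shape length-2 integer `(n_rows, n_cols)`.
#' @param pitch_px lattice pitch in pixels (> `pit_width_px`).
#' @param pit_width_px pit side length in pixels (>= 2).
#' @param depth_nm pit depth in nm (>= 0).
#' @param spec background [background_spec()].
#' @param seed seed for stochastic background components.
#' @param pixel_size_nm pixel size to attach.
#' @return An `afm_scene` (features hold one grating descriptor).
#' @export
make_grating <- function(shape, pitch_px, pit_width_px, depth_nm,
                         spec = background_spec(), seed = 1L, pixel_size_nm = 1) {
  if (pit_width_px < 2) stop("pit_width_px must be >= 2", call. = FALSE)
  if (pitch_px <= pit_width_px)
    stop("pitch_px must exceed pit_width_px (pits would overlap)", call. = FALSE)
  bg <- make_background(shape, spec, seed = seed, pixel_size_nm = pixel_size_nm)
  nr <- shape[1L]; nc <- shape[2L]
  off <- floor((pitch_px - pit_width_px) / 2)
  in_pit_1d <- function(n) ((seq_len(n) - 1 - off) %% pitch_px) < pit_width_px &
                           (seq_len(n) - 1) >= off
  inc <- outer(in_pit_1d(nr), in_pit_1d(nc), `&`)
  relief <- -depth_nm * inc
  mask <- foreground_mask(inc, polarity = "concave")
  structure(list(image = set_heights(bg, bg$heights + relief),
                 truth_background = bg,
                 truth_relief = set_heights(bg, relief),
                 truth_mask = mask,
                 features = list(list(kind = "grating", pitch_px = pitch_px,
                                      pit_width_px = pit_width_px,
                                      depth_nm = depth_nm, offset_px = off)),
                 noise_sd = spec$noise_sd),
            class = "afm_scene")
}

#' Generate a field of spherical caps on a background
#'
#' Places `n_caps` non-overlapping caps on a jittered grid with radii and
#' apex heights drawn uniformly from the given ranges -- the typical
#' surface-nanobubble population used to exercise segmentation and
#' two-pass flattening.
#'
#' @param shape length-2 integer `(n_rows, n_cols)`.
#' @param n_caps number of caps.
#' @param radius_range,height_range length-2 numeric ranges (px, nm).
#' @param spec background [background_spec()].
#' @param seed integer seed (controls placement, sizes and background).
#' @return An `afm_scene`.
#' @export
make_cap_field <- function(shape, n_caps = 20L,
                           radius_range = c(6, 11), height_range = c(8, 25),
                           spec = background_spec(), seed = 1L) {
  bg <- make_background(shape, spec, seed = seed)
  feats <- with_seed(seed + 1L, {
    g <- ceiling(sqrt(n_caps))
    cells <- utils::head(sample(g * g), n_caps)
    cell_h <- (shape[1L] - 2) / g; cell_w <- (shape[2L] - 2) / g
    lapply(cells, function(cl) {
      gi <- (cl - 1L) %/% g; gj <- (cl - 1L) %% g
      r <- stats::runif(1L, radius_range[1L], radius_range[2L])
      h <- stats::runif(1L, height_range[1L], height_range[2L])
      jit <- max(0, min(cell_h, cell_w) / 2 - r - 2)
      ctr <- c(1 + cell_h * (gi + 0.5) + stats::runif(1L, -jit, jit),
               1 + cell_w * (gj + 0.5) + stats::runif(1L, -jit, jit))
      ctr <- pmin(pmax(ctr, r + 2), shape - r - 2)
      cap_feature(ctr, r, h)
    })
  })
  add_features(bg, feats, noise = spec$noise_sd)
}

#' Build a scene from a YAML configuration
#'
#' The configuration holds `shape`, `seed`, a `background` block
#' (fields of [background_spec()]) and either a `features` list (each with
#' `kind`, `center`, `radius`, `height`/`depth`) or a `grating` block
#' (`pitch_px`, `pit_width_px`, `depth_nm`).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return An `afm_scene`.
#' @export
scene_from_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  shape <- as.integer(unlist(cfg$shape))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  bgl <- cfg$background
  if (!is.null(bgl$sinusoids))
    bgl$sinusoids <- do.call(rbind, lapply(bgl$sinusoids, as.data.frame))
  if (!is.null(bgl$bow)) bgl$bow <- unlist(bgl$bow)
  if (!is.null(bgl$tilt)) bgl$tilt <- as.numeric(unlist(bgl$tilt))
  spec <- do.call(background_spec, if (is.null(bgl)) list() else bgl)
  if (!is.null(cfg$grating)) {
    g <- cfg$grating
    return(make_grating(shape, g$pitch_px, g$pit_width_px, g$depth_nm,
                        spec = spec, seed = seed))
  }
  feats <- lapply(cfg$features, function(f) {
    ctr <- as.numeric(unlist(f$center))
    switch(f$kind,
           cap = cap_feature(ctr, f$radius, f$height),
           pit = pit_feature(ctr, f$radius, f$depth),
           stop("unknown feature kind: ", f$kind, call. = FALSE))
  })
  bg <- make_background(shape, spec, seed = seed)
  add_features(bg, feats, noise = spec$noise_sd)
}
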