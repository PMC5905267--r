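poly3_background <- function(nr, nc, seed) {
  u <- afmflatten:::norm_coord(seq_len(nr), nr)
  v <- afmflatten:::norm_coord(seq_len(nc), nc)
  ex <- afmflatten:::monomials_2d(3)
  set.seed(seed)
  coef <- rnorm(nrow(ex), sd = 15)
  m <- matrix(0, nr, nc)
  for (k in seq_len(nrow(ex)))
    m <- m + coef[k] * outer(u^ex$i[k], v^ex$j[k])
  m
}

test_that("every method recovers a degree-3 background exactly under a true mask", {
  for (seed in c(2, 5)) {
    bg <- height_image(poly3_background(96, 96, seed))
    sc <- add_features(bg, list(cap_feature(c(30, 30), 10, 20),
                                pit_feature(c(70, 60), 9, 30)))
    for (m in c("mef_line", "mef_surface", "swcf", "swsf")) {
      fr <- flatten_image(sc$image, sc$truth_mask, method = m,
                          window = c(24, 24))
      bgpx <- !sc$truth_mask$included
      d <- (fr$background_est$heights - bg$heights)[bgpx]
      expect_lt(max(abs(d - mean(d))), 1e-6)
      # features survive: flattened equals the relief on foreground pixels
      expect_lt(max(abs((fr$flattened$heights -
                           sc$truth_relief$heights)[bgpx])), 1e-6)
    }
  }
})

test_that("the flattened/background decomposition is exact and shift-equivariant", {
  sc <- cap_pit_scene()
  for (m in c("direct_line", "mef_line", "mef_surface", "swcf", "swsf")) {
    mask <- if (m == "direct_line") NULL else sc$truth_mask
    fr <- flatten_image(sc$image, mask, method = m, window = c(24, 24))
    expect_identical(sc$image$heights - fr$flattened$heights,
                     fr$background_est$heights)
    expect_lt(max(abs(fr$flattened$heights + fr$background_est$heights -
                        sc$image$heights)), 1e-9)
    shifted <- height_image(sc$image$heights + 11.25)
    fr2 <- flatten_image(shifted, mask, method = m, window = c(24, 24))
    expect_lt(max(abs(fr2$flattened$heights - fr$flattened$heights)), 1e-9)
    expect_lt(max(abs(fr2$background_est$heights -
                        fr$background_est$heights - 11.25)), 1e-9)
  }
})

test_that("zero images flatten to zero", {
  fr <- flatten_lines(height_image(matrix(0, 16, 16)))
  expect_equal(fr$flattened$heights, matrix(0, 16, 16))
  expect_equal(fr$background_est$heights, matrix(0, 16, 16))
})

test_that("direct line flattening digs dark stripes; mask exclusion does not", {
  sp <- background_spec(tilt = c(0.08, 0.15))
  sc <- add_features(make_background(c(128, 128), sp, seed = 4),
                     list(cap_feature(c(64, 64), 14, 25)))
  crossing <- apply(sc$truth_mask$included, 1, any)
  bg <- !sc$truth_mask$included
  sel <- bg & matrix(crossing, 128, 128)

  direct <- flatten_lines(sc$image, NULL)
  expect_lt(mean(direct$flattened$heights[sel]), 0)
  mef <- flatten_lines(sc$image, sc$truth_mask)
  expect_lt(abs(mean(mef$flattened$heights[sel])), 1e-6)
})

test_that("a single surface cannot follow per-row drift but line fits can", {
  sp <- background_spec(tilt = c(0.05, 0.1), drift_sd = 1.5)
  sc <- add_features(make_background(c(96, 96), sp, seed = 13),
                     list(cap_feature(c(40, 40), 10, 20)))
  rs_line <- residual_stats(flatten_lines(sc$image, sc$truth_mask),
                            sc$truth_background, sc$truth_mask)
  rs_surf <- residual_stats(flatten_surface(sc$image, sc$truth_mask),
                            sc$truth_background, sc$truth_mask)
  expect_gt(rs_surf$rms, rs_line$rms)
})

test_that("pits keep their depth through surface flattening", {
  sp <- background_spec(tilt = c(0.1, 0.2))
  sc <- add_features(make_background(c(96, 96), sp, seed = 6),
                     list(pit_feature(c(48, 48), 12, 60)))
  fr <- flatten_surface(sc$image, sc$truth_mask)
  prof <- cross_section(fr$flattened, 48, "row")
  expect_lt(abs(feature_depth(prof) - 60) / 60, 0.01)
})

test_that("fitting along the slow axis transposes the problem", {
  sp <- background_spec(tilt = c(0.3, 0))  # trend along rows only
  bg <- make_background(c(48, 48), sp, seed = 1)
  fr_slow <- flatten_lines(bg, axis = "slow")
  expect_lt(max(abs(fr_slow$flattened$heights)), 1e-9)
  tr <- transpose_image(bg)
  fr_fast_t <- flatten_lines(tr, axis = "fast")
  expect_equal(t(fr_fast_t$flattened$heights), fr_slow$flattened$heights,
               tolerance = 1e-12)
})

test_that("swcf equals a straightforward single-pass reference implementation", {
  swcf_ref <- function(m, w, order = 3) {
    nr <- nrow(m); nc <- ncol(m)
    base <- matrix(0, nr, nc)
    for (r in seq_len(nr)) {
      acc <- numeric(nc); cnt <- numeric(nc)
      for (a in 1:(nc - w + 1)) {
        sel <- a:(a + w - 1)
        x <- 2 * (sel - 1) / (nc - 1) - 1
        fit <- stats::lm.fit(outer(x, 0:order, `^`), m[r, sel])
        acc[sel] <- acc[sel] + fit$fitted.values
        cnt[sel] <- cnt[sel] + 1
      }
      base[r, ] <- acc / cnt
    }
    base
  }
  sp <- background_spec(sinusoids = data.frame(amplitude = 50, period = 128,
                                               phase = 0.3, axis = "col"))
  bg <- make_background(c(16, 256), sp, seed = 1)
  fr <- swcf(bg, NULL, window = 16)
  ref <- swcf_ref(bg$heights, 16)
  expect_lt(max(abs(fr$background_est$heights - ref)), 1e-9)

  # residual bounded by the oracle's own residual plus slack, and under
  # 5% of the background RMS
  resid_ref <- bg$heights - ref
  rms_ref <- sqrt(mean((resid_ref - mean(resid_ref))^2))
  rs <- residual_stats(fr, bg, NULL)
  expect_lte(rs$rms, rms_ref * (1 + 1e-9))
  expect_lt(rs$rms, 0.05 * sqrt(mean((bg$heights - mean(bg$heights))^2)))
})

test_that("cubic backgrounds are exact for any sliding window (closure)", {
  bg <- height_image(poly3_background(48, 64, 3))
  expect_lt(max(abs(swcf(bg, NULL, window = 12)$flattened$heights)), 1e-6)
  expect_lt(max(abs(swsf(bg, NULL, window = c(12, 16))$flattened$heights)),
            1e-6)
})

test_that("sliding-window residuals grow with window size on complex backgrounds", {
  sc <- add_features(make_background(c(160, 160), complex_bg_spec(), seed = 3),
                     list(cap_feature(c(50, 60), 7, 20),
                          cap_feature(c(110, 100), 7, 16)))
  rms_c <- rms_s <- numeric(0)
  for (w in c(16, 32, 64)) {
    rms_c <- c(rms_c, residual_stats(swcf(sc$image, sc$truth_mask, window = w),
                                     sc$truth_background, sc$truth_mask)$rms)
    rms_s <- c(rms_s, residual_stats(
      swsf(sc$image, sc$truth_mask, window = c(w, w)),
      sc$truth_background, sc$truth_mask)$rms)
  }
  expect_true(all(diff(rms_c) >= 0))
  expect_true(all(diff(rms_s) >= 0))
})

test_that("swsf preserves apex heights on a complex background", {
  sc <- add_features(make_background(c(160, 160), complex_bg_spec(), seed = 3),
                     list(cap_feature(c(50, 60), 7, 20),
                          cap_feature(c(110, 100), 7, 16)))
  fr <- swsf(sc$image, sc$truth_mask, window = c(16, 16))
  for (f in sc$features) {
    ring <- afmflatten:::cap_relief(dim(sc$image$heights), f$center,
                                    f$radius + 3, 1) > 0 &
      !sc$truth_mask$included
    apex <- fr$flattened$heights[f$center[1], f$center[2]] -
      mean(fr$flattened$heights[ring])
    expect_lt(abs(apex - f$height) / f$height, 0.02)
  }
})

test_that("fitting along the drift-free fast axis beats the rotated image", {
  sp <- background_spec(tilt = c(0, 0.05), drift_sd = 1.5, noise_sd = 0.2)
  sc <- add_features(make_background(c(128, 128), sp, seed = 7),
                     list(cap_feature(c(50, 50), 10, 20)))
  rs_fast <- residual_stats(swcf(sc$image, sc$truth_mask, window = 32),
                            sc$truth_background, sc$truth_mask)
  rot_img <- rotate_image_90(sc$image)
  rot_truth <- rotate_image_90(sc$truth_background)
  rot_mask <- foreground_mask(rotate_image_90(
    height_image(sc$truth_mask$included * 1))$heights > 0.5)
  rs_rot <- residual_stats(swcf(rot_img, rot_mask, window = 32),
                           rot_truth, rot_mask)
  expect_lt(rs_fast$rms, rs_rot$rms)
})

test_that("background-starved lines fall back to neighbour interpolation", {
  sp <- background_spec(tilt = c(0.2, 0.3))
  bg <- make_background(c(48, 48), sp, seed = 1)
  mask <- matrix(FALSE, 48, 48)
  mask[20:23, ] <- TRUE  # four fully masked lines
  fr <- flatten_lines(bg, mask)
  expect_equal(fr$params$fallback_lines, 4L)
  expect_lt(max(abs(fr$flattened$heights)), 1e-6)

  # every line masked -> no fit possible
  expect_error(flatten_lines(bg, matrix(TRUE, 48, 48)), "mask excludes")
})

test_that("window validation catches impossible sizes", {
  bg <- make_background(c(32, 32), background_spec(tilt = c(0, 0.1)), 1)
  expect_error(swcf(bg, NULL, window = 4, order = 3), ">= order")
  expect_error(swcf(bg, NULL, window = 40), "wider")
  expect_error(swsf(bg, NULL, window = c(40, 8)), "larger")
})
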