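test_that("complement flips polarity and is an involution up to a constant", {
  sc <- cap_pit_scene()
  comp <- complement_image(sc$image)
  twice <- complement_image(comp)
  expect_equal(twice$heights - sc$image$heights,
               matrix((twice$heights - sc$image$heights)[1], 128, 128),
               tolerance = 1e-9)
  expect_equal(complement_image(height_image(matrix(4, 8, 8)))$heights,
               matrix(0, 8, 8))

  # a pit on a flat background becomes a cap of the same magnitude
  pit <- add_features(make_background(c(64, 64), background_spec(), 1),
                      list(pit_feature(c(32, 32), 10, 45)))
  cm <- complement_image(pit$image)
  expect_equal(max(cm$heights) - min(cm$heights), 45)
  expect_equal(which.max(cm$heights), which.min(pit$image$heights))
})

test_that("adaptive thresholding matches a brute-force local-mean oracle", {
  # constant images are empty at any offset, including 0 (strict inequality)
  const <- height_image(matrix(2, 16, 16))
  expect_false(any(adaptive_threshold(const, 5, 0.5)))
  expect_false(any(adaptive_threshold(const, 5, 0)))

  m <- matrix(0, 8, 8)
  m[4:5, 4:5] <- 10
  got <- adaptive_threshold(height_image(m), 5, 1)
  expect_true(all(got[4:5, 4:5]))

  brute <- matrix(NA, 8, 8)
  for (r in 1:8) for (c in 1:8) {
    rs <- pmin(pmax(r + (-2:2), 1), 8)
    cs <- pmin(pmax(c + (-2:2), 1), 8)
    brute[r, c] <- m[r, c] > mean(m[rs, cs]) + 1
  }
  expect_identical(got, brute)

  set.seed(8)
  m2 <- matrix(rnorm(24 * 20, sd = 3), 24, 20)
  got2 <- adaptive_threshold(height_image(m2), 7, 0.5)
  brute2 <- matrix(NA, 24, 20)
  for (r in 1:24) for (c in 1:20) {
    rs <- pmin(pmax(r + (-3:3), 1), 24)
    cs <- pmin(pmax(c + (-3:3), 1), 20)
    brute2[r, c] <- m2[r, c] > mean(m2[rs, cs]) + 0.5
  }
  expect_identical(got2, brute2)

  expect_error(adaptive_threshold(const, 17, 1), "smaller")
  expect_error(adaptive_threshold(const, 4, 1), "odd")
})

test_that("8-connected labelling treats corner contact as one component", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE
  m[4, 4] <- TRUE          # touches only diagonally
  m[8:9, 8:9] <- TRUE      # separate blob
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[4, 4], lab[2, 2])
  expect_equal(max(label_components(matrix(FALSE, 4, 4))), 0L)
})

test_that("initial contours trace components above the area cutoff", {
  expect_length(initial_contours(matrix(FALSE, 32, 32), 10), 0)

  rho <- sqrt(outer((1:64 - 32)^2, rep(1, 64)) +
                outer(rep(1, 64), (1:64 - 32)^2))
  disk <- rho <= 10
  cs <- initial_contours(disk, 20)
  expect_length(cs, 1)
  area <- afmflatten:::polygon_area(cs[[1]]$points)
  expect_lt(abs(area - 100 * pi) / (100 * pi), 0.1)

  two <- disk
  two[5:6, 5:6] <- TRUE  # 4 px, below min_area
  expect_length(initial_contours(two, 20), 1)
})

test_that("a contour started on a sharp rim stays there", {
  rho <- sqrt(outer((1:96 - 48)^2, rep(1, 96)) +
                outer(rep(1, 96), (1:96 - 48)^2))
  img <- height_image((rho <= 15) * 20)
  theta <- seq(0, 2 * pi, length.out = 41)[-41]
  c0 <- afmflatten:::new_contour(cbind(48 + 15 * sin(theta),
                                       48 + 15 * cos(theta)))
  cf <- expand_contour(img, c0, snake_params())
  radii <- sqrt(rowSums(sweep(cf$points, 2, c(48, 48))^2))
  expect_lt(mean(abs(radii - 15)), 1)
})

test_that("contour expansion recovers the cap footprint from a small seed", {
  sp <- background_spec(tilt = c(0.05, 0.08), noise_sd = 0.3)
  sc <- add_features(make_background(c(96, 96), sp, seed = 5),
                     list(cap_feature(c(48, 48), 10, 15)))
  fm <- segment_features(sc$image, "convex")
  expect_equal(max(fm$components), 1L)
  expect_lt(abs(sum(fm$included) - sum(sc$truth_mask$included)) /
              sum(sc$truth_mask$included), 0.1)
  ix <- which(fm$included, arr.ind = TRUE)
  expect_lt(sqrt(sum((colMeans(ix) - c(48, 48))^2)), 2)
})

test_that("raising the internal-energy coefficients restrains expansion", {
  sp <- background_spec(tilt = c(0.05, 0.08), noise_sd = 0.3)
  sc <- add_features(make_background(c(128, 128), sp, seed = 11),
                     list(cap_feature(c(42, 40), 14, 20)))
  thr <- EBImage::opening(adaptive_threshold(sc$image, 31, 10) * 1,
                          EBImage::makeBrush(3, "box")) > 0.5
  c0 <- initial_contours(thr, 20)[[1]]
  areas <- vapply(c(1, 3, 8), function(s) {
    cf <- expand_contour(sc$image, c0,
                         snake_params(alpha = 0.4 * s, beta = 0.4 * s))
    afmflatten:::polygon_area(cf$points)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
  # doubling from the defaults does not enlarge the contour (up to
  # rasterization-level jitter)
  twice <- expand_contour(sc$image, c0, snake_params(alpha = 0.8, beta = 0.8))
  expect_lte(afmflatten:::polygon_area(twice$points), areas[1] * 1.01)
  # and the defaults genuinely expanded the under-estimating seed
  expect_gt(areas[1], 2 * afmflatten:::polygon_area(c0$points))
})

test_that("cap and pit are found with the right polarity and good overlap", {
  sc <- cap_pit_scene()
  fm <- segment_features(sc$image, "both")
  expect_equal(max(fm$components), 2L)
  expect_setequal(fm$polarity, c("convex", "concave"))
  for (k in 1:2)
    expect_gte(component_best_iou(fm, k, sc$truth_mask), 0.7)

  only_convex <- segment_features(sc$image, "convex")
  expect_equal(max(only_convex$components), 1L)
  expect_equal(only_convex$polarity, "convex")
})

test_that("segmentation is deterministic and polarity-dual", {
  sc <- cap_pit_scene()
  a <- segment_features(sc$image, "both")
  b <- segment_features(sc$image, "both")
  expect_identical(a$included, b$included)

  conc <- segment_features(sc$image, "concave")
  dual <- segment_features(complement_image(sc$image), "convex")
  expect_identical(conc$included, dual$included)
})

test_that("flat noisy images yield an empty mask at a safe offset", {
  flat <- make_background(c(96, 96), background_spec(noise_sd = 0.5), seed = 3)
  fm <- segment_features(flat, "both", offset_nm = 2.5)
  expect_false(any(fm$included))
  expect_equal(max(fm$components), 0L)
})

test_that("mask dilation grows components and keeps polarity labels", {
  sc <- cap_pit_scene()
  fm <- foreground_mask(sc$truth_mask$included, sc$truth_mask$polarity)
  fd <- mask_dilate(fm, 2)
  expect_gt(sum(fd$included), sum(fm$included))
  expect_true(all(fm$included[fd$included == FALSE] == FALSE))
  expect_setequal(fd$polarity, c("convex", "concave"))
  expect_identical(mask_dilate(fm, 0)$included, fm$included)
})
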