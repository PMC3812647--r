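test_that("normalising an identical pair recovers the identity map", {
  pre <- varied_scene(seed = 5)
  post <- ms_scene(pre$bands, pre$grid, "2007-09-01")
  res <- normalize_radiometry(scene_pair(pre, post))
  model <- attr(res, "normalization_model")
  expect_equal(model$gain, rep(1, 3), tolerance = 1e-9)
  expect_equal(model$offset, rep(0, 3), tolerance = 1e-9)
  expect_equal(res$post$bands$NIR, pre$bands$NIR, tolerance = 1e-9)
})

test_that("an exact affine distortion is inverted in closed form", {
  pre <- varied_scene(grid = tiny_grid(15, 15), seed = 7)
  post <- ms_scene(lapply(pre$bands, function(b) 2 * b + 5), pre$grid,
                   "2007-09-01")
  res <- normalize_radiometry(scene_pair(pre, post))
  model <- attr(res, "normalization_model")
  # oracle: least squares on all pixels of y = pre, x = 2*pre + 5 gives
  # slope 0.5 and intercept -2.5 exactly in the noise-free case
  for (b in c("RED", "NIR", "MIR")) {
    fit <- stats::lm(as.vector(pre$bands[[b]]) ~ as.vector(post$bands[[b]]))
    expect_equal(unname(stats::coef(fit)[2]), 0.5, tolerance = 1e-9)
    expect_equal(model$gain[model$band == b], 0.5, tolerance = 1e-6)
    expect_equal(model$offset[model$band == b], -2.5, tolerance = 1e-6)
  }
  expect_equal(res$post$bands$RED, pre$bands$RED, tolerance = 1e-6)
})

test_that("normalisation is idempotent and method none is a no-op", {
  pre <- varied_scene(grid = tiny_grid(15, 15), seed = 8)
  post <- ms_scene(lapply(pre$bands, function(b) 1.3 * b + 0.02), pre$grid,
                   "2007-09-01")
  pair <- scene_pair(pre, post)
  expect_identical(normalize_radiometry(pair, method = "none"), pair)
  once <- normalize_radiometry(pair)
  twice <- normalize_radiometry(once)
  model <- attr(twice, "normalization_model")
  expect_equal(model$gain, rep(1, 3), tolerance = 1e-6)
  expect_equal(model$offset, rep(0, 3), tolerance = 1e-6)
})

test_that("normalisation failure modes are explicit", {
  pre <- uniform_scene(0.1, 0.4, 0.2, grid = tiny_grid(3, 3))
  post <- uniform_scene(0.1, 0.4, 0.2, grid = tiny_grid(3, 3),
                        date = "2007-09-01")
  expect_error(normalize_radiometry(scene_pair(pre, post), min_pif = 100),
               "9")
  # constant post band against a varying pre band cannot be fit
  pre2 <- varied_scene(grid = tiny_grid(15, 15), seed = 9)
  cb <- lapply(pre2$bands, function(b) matrix(0.2, 15, 15))
  post2 <- ms_scene(cb, pre2$grid, "2007-09-01")
  expect_error(normalize_radiometry(scene_pair(pre2, post2), min_pif = 10),
               "zero-variance")
})

test_that("mask rules reproduce the hand-evaluated examples", {
  # bright low-NDVI pixel: albedo 0.41 >= 0.35 and NDVI 0.024 <= 0.10
  cloudy <- uniform_scene(0.40, 0.42, 0.38)
  m <- build_masks(cloudy)
  expect_true(all(m$cloud))
  expect_false(any(m$water | m$shadow | m$nodata))
  # healthy vegetation triggers nothing
  veg <- build_masks(uniform_scene(0.05, 0.45, 0.18))
  expect_false(any(mask_any(veg)))
  # dark negative-NDVI pixel is water (and dark enough for shadow)
  wat <- build_masks(uniform_scene(0.04, 0.02, 0.01))
  expect_true(all(wat$water))
  # all-nodata scene: nodata mask only
  g <- tiny_grid()
  nas <- ms_scene(list(RED = matrix(NA_real_, 4, 4),
                       NIR = matrix(NA_real_, 4, 4)), g, "2007-01-01")
  mn <- build_masks(nas)
  expect_true(all(mn$nodata))
  expect_false(any(mn$cloud | mn$water | mn$shadow))
})

test_that("change magnitude is the Euclidean band-difference norm", {
  pre <- uniform_scene(0.1, 0.4, 0.2)
  b <- pre$bands
  b$RED[2, 2] <- b$RED[2, 2] + 3
  b$NIR[2, 2] <- b$NIR[2, 2] + 4
  post <- ms_scene(b, pre$grid, "2007-09-01")
  pair <- scene_pair(pre, post)
  mag <- change_vector_magnitude(pair, c("RED", "NIR"))
  expect_equal(mag$values[2, 2], 5)
  expect_equal(sum(mag$values), 5)   # all other pixels zero
  expect_equal(change_vector_magnitude(pair, "RED")$values[2, 2], 3)
  # symmetry under swapping the dates
  rev <- scene_pair(ms_scene(b, pre$grid, "2007-06-01"),
                    ms_scene(pre$bands, pre$grid, "2007-09-01"))
  expect_equal(change_vector_magnitude(rev, c("RED", "NIR"))$values,
               mag$values)
  expect_error(change_vector_magnitude(pair, character(0)), "empty")
})

test_that("change thresholding follows the fixed and robust rules", {
  g <- geo_grid(10, 10, 30)
  m <- matrix(0.01, 10, 10)
  m[5, 5] <- 0.9
  # robust rule: median 0.01, MAD 0 -> threshold 0.01; only the outlier
  cm <- change_mask(geo_raster(m, g), method = "robust", k = 3)
  expect_equal(sum(cm$changed), 1)
  expect_true(cm$changed[5, 5])
  # all-zero magnitude: nothing changes
  cm0 <- change_mask(geo_raster(matrix(0, 10, 10), g))
  expect_equal(sum(cm0$changed), 0)
  # strict inequality at a fixed threshold
  mf <- geo_raster(matrix(c(0.4, 0.5, 0.6), 1, 3), geo_grid(1, 3, 30))
  cf <- change_mask(mf, method = "fixed", t = 0.5)
  expect_equal(as.vector(cf$changed), c(FALSE, FALSE, TRUE))
  expect_error(change_mask(geo_raster(matrix(NA_real_, 2, 2),
                                      geo_grid(2, 2, 30))), "nodata")
})

test_that("raising the change threshold never adds changed pixels", {
  set.seed(42)
  g <- geo_grid(20, 20, 30)
  mag <- geo_raster(matrix(rexp(400, 5), 20, 20), g)
  prev <- change_mask(mag, method = "fixed", t = 0)$changed
  for (t in c(0.1, 0.2, 0.4, 0.8)) {
    cur <- change_mask(mag, method = "fixed", t = t)$changed
    expect_true(all(prev | !cur))   # cur subset of prev
    prev <- cur
  }
})
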