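test_that("majority filtering matches the hand-derived cases", {
  g <- geo_grid(9, 9, 30)
  # isolated burnt pixel is removed (majority 1/9)
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_equal(sum(median_filter(burn_raster(m, g))$values), 0)
  # a solid 5x5 block keeps its interior and edges; the four corners have
  # only 4 burnt pixels in their 3x3 neighbourhood and are shaved off
  m2 <- matrix(FALSE, 9, 9); m2[3:7, 3:7] <- TRUE
  shaved <- m2
  shaved[cbind(c(3, 3, 7, 7), c(3, 7, 3, 7))] <- FALSE
  got <- median_filter(burn_raster(m2, g))$values
  expect_identical(got, shaved)
  expect_identical(got, oracle_majority(m2, 3))
  # a single unburnt hole is filled (majority 8/9)
  m3 <- m2; m3[5, 5] <- FALSE
  expect_identical(median_filter(burn_raster(m3, g))$values, shaved)
  expect_error(median_filter(burn_raster(m, g), 4), "odd")
})

test_that("majority filter agrees with brute force on random grids", {
  for (seed in 1:6) {
    set.seed(seed)
    nr <- sample(5:12, 1); nc <- sample(5:12, 1)
    m <- matrix(runif(nr * nc) < 0.4, nr, nc)
    g <- geo_grid(nr, nc, 30)
    for (k in c(3, 5))
      expect_identical(median_filter(burn_raster(m, g), k)$values,
                       oracle_majority(m, k),
                       info = paste("seed", seed, "k", k))
  }
})

test_that("minimum-mapping-unit removal obeys the strictly-below rule", {
  # 30 m pixels are 0.09 ha: 11 px = 0.99 ha goes, 12 px = 1.08 ha stays
  g30 <- geo_grid(10, 30, 30)
  m <- matrix(FALSE, 10, 30)
  m[2, 1:11] <- TRUE          # 0.99 ha line
  m[6, 1:12] <- TRUE          # 1.08 ha line
  out <- remove_small_scars(burn_raster(m, g30), mmu_ha = 1)
  expect_equal(sum(out$values[2, ]), 0)
  expect_equal(sum(out$values[6, ]), 12)
  # 20 m pixels: 25 px are exactly 1.00 ha and are kept
  g20 <- geo_grid(10, 10, 20)
  m2 <- matrix(FALSE, 10, 10); m2[3:7, 3:7] <- TRUE
  expect_equal(sum(remove_small_scars(burn_raster(m2, g20), 1)$values), 25)
  # empty raster passes through
  empty <- burn_raster(matrix(FALSE, 5, 5), geo_grid(5, 5, 30))
  expect_equal(sum(remove_small_scars(empty, 1)$values), 0)
})

test_that("small-object removal matches flood-fill brute force and is idempotent", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(15 * 15) < 0.35, 15, 15)
    g <- geo_grid(15, 15, 30)
    for (conn in c(4, 8)) {
      got <- remove_small_scars(burn_raster(m, g), 0.5, conn)
      expect_identical(got$values, oracle_remove_small(m, 0.5, 0.09, conn),
                       info = paste("seed", seed, "conn", conn))
      expect_identical(remove_small_scars(got, 0.5, conn)$values, got$values)
    }
  }
})

test_that("polygonization yields exact areas, holes and connectivity behaviour", {
  g <- geo_grid(14, 14, 30)
  # 10x10 block: one polygon of 9 ha
  m <- matrix(FALSE, 14, 14); m[3:12, 3:12] <- TRUE
  sc <- polygonize(burn_raster(m, g))
  expect_equal(nrow(sc), 1)
  expect_equal(sc$area_ha, 9)
  # with a 2x2 enclave: one polygon, one hole, (100-4) * 0.09 ha
  m2 <- m; m2[7:8, 7:8] <- FALSE
  sc2 <- polygonize(burn_raster(m2, g))
  expect_equal(nrow(sc2), 1)
  expect_equal(sc2$area_ha, 8.64)
  expect_equal(length(sc2$geometry[[1]][[1]]), 2)   # exterior + 1 hole
  # diagonal-touching pixels: 4-connectivity splits, 8 joins
  d <- matrix(FALSE, 4, 4); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  bd <- burn_raster(d, geo_grid(4, 4, 30))
  expect_equal(nrow(polygonize(bd, connectivity = 4)), 2)
  sc8 <- polygonize(bd, connectivity = 8)
  expect_equal(nrow(sc8), 1)
  expect_equal(sc8$area_ha, 2 * 0.09, tolerance = 1e-9)
  # empty raster gives an empty catalog
  expect_equal(nrow(polygonize(burn_raster(matrix(FALSE, 3, 3),
                                           geo_grid(3, 3, 30)))), 0)
})

test_that("pixel area is conserved through polygonization on random rasters", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(runif(20 * 20) < 0.45, 20, 20)
    g <- geo_grid(20, 20, 30)
    sc <- polygonize(burn_raster(m, g))
    expect_equal(sum(sc$area_ha), sum(m) * 0.09, tolerance = 1e-9)
    # and rasterizing the polygons back recovers the raster exactly
    expect_identical(rasterize_scars(sc, g), m)
  }
})

test_that("event aggregation groups by boundary distance", {
  sq <- function(x0, side = 90)
    list(list(matrix(c(x0, 0, x0 + side, 0, x0 + side, side, x0, side),
                     ncol = 2, byrow = TRUE)))
  scars <- scar_set(list(sq(0), sq(140)), crs = "EPSG:32634")  # 50 m gap
  agg <- aggregate_scars(scars, gap_m = 100)
  expect_equal(length(unique(agg$event_id)), 1)
  expect_equal(unique(agg$event_area_ha), sum(scars$area_ha))
  agg2 <- aggregate_scars(scars, gap_m = 10)
  expect_equal(length(unique(agg2$event_id)), 2)
  # gap 0 groups only touching polygons
  touching <- scar_set(list(sq(0), sq(90)), crs = "EPSG:32634")
  expect_equal(length(unique(aggregate_scars(touching, 0)$event_id)), 1)
  expect_equal(length(unique(aggregate_scars(scars, 0)$event_id)), 2)
})

test_that("land-cover attribution splits area by zonal pixel counts", {
  g <- geo_grid(10, 10, 30)
  m <- matrix(FALSE, 10, 10); m[1:10, 1:10] <- TRUE
  sc <- polygonize(burn_raster(m, g))
  # uniform class
  lc_u <- geo_raster(matrix(312L, 10, 10), g)
  a1 <- attribute_scars(sc, lc_u)
  expect_equal(a1$lc_312, 9)
  # 60/40 split by columns
  lc2 <- geo_raster(matrix(rep(c(312L, 323L), c(6, 4) * 10), 10, 10,
                           byrow = FALSE), g)
  # build by columns: first 6 columns 312, last 4 columns 323
  vals <- matrix(323L, 10, 10); vals[, 1:6] <- 312L
  a2 <- attribute_scars(sc, geo_raster(vals, g))
  expect_equal(a2$lc_312 / a2$lc_323, 60 / 40)
  expect_equal(a2$lc_312 + a2$lc_323, a2$area_ha, tolerance = 0.09)
  # no land cover: only area_ha refreshed
  a3 <- attribute_scars(sc)
  expect_false(any(grepl("^lc_", names(a3))))
  # CRS mismatch is an error
  lc_bad <- geo_raster(matrix(312L, 10, 10), geo_grid(10, 10, 30,
                                                      crs = "EPSG:2100"))
  expect_error(attribute_scars(sc, lc_bad), "CRS")
})
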