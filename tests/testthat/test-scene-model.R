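test_that("grid construction validates geometry and units", {
  g <- geo_grid(100, 50, 30)
  expect_equal(pixel_area_ha(g), 0.09)
  expect_equal(pixel_area_ha(geo_grid(10, 10, 20)), 0.04)
  expect_error(geo_grid(0, 10, 30))
  expect_error(geo_grid(10, 10, -1))
  expect_error(geo_grid(10, 10, 30, crs = "EPSG:4326"), "projected CRS")
})

test_that("scene construction enforces band roles and shapes", {
  g <- tiny_grid()
  m <- matrix(0.1, 4, 4)
  expect_error(ms_scene(list(RED = m), g, "2007-01-01"), "NIR")
  expect_error(ms_scene(list(RED = m, NIR = matrix(0.1, 3, 3)), g,
                        "2007-01-01"), "dimensions")
  expect_error(ms_scene(list(RED = m, NIR = m, XYZ = m), g, "2007-01-01"),
               "roles")
  s <- ms_scene(list(RED = m, NIR = m), g, "2007-01-01", nodata_value = 0.1)
  expect_true(all(is.na(s$bands$RED)))
})

test_that("scene pairs must be co-registered and time-ordered", {
  a <- uniform_scene(0.1, 0.4, 0.2, date = "2007-06-01")
  b <- uniform_scene(0.1, 0.4, 0.2, date = "2007-09-01")
  expect_s3_class(scene_pair(a, b), "scene_pair")
  expect_error(scene_pair(b, a), "precede")
  c <- uniform_scene(0.1, 0.4, 0.2, grid = tiny_grid(5, 5),
                     date = "2007-09-01")
  expect_error(scene_pair(a, c), "co-registered")
})

test_that("ascii-grid rasters round-trip values and georeferencing", {
  dir <- withr::local_tempdir()
  g <- geo_grid(6, 5, 30, origin_x = 500000, origin_y = 4200000)
  set.seed(1)
  vals <- matrix(round(runif(30), 6), 6, 5)
  vals[2, 3] <- NA
  p <- file.path(dir, "layer.asc")
  write_asc(geo_raster(vals, g, "layer"), p)
  back <- read_asc(p)
  expect_equal(back$values, vals, tolerance = 1e-9)
  expect_equal(back$grid$pixel_size_m, 30)
  expect_equal(back$grid$origin_x, 500000)
  expect_equal(back$grid$origin_y, 4200000)
  expect_identical(back$grid$crs, g$crs)
})

test_that("scenes round-trip through per-band files with metadata", {
  dir <- withr::local_tempdir()
  s <- varied_scene()
  stem <- file.path(dir, "scene")
  write_scene(s, stem)
  back <- read_scene(stem)
  expect_equal(back$bands$RED, s$bands$RED, tolerance = 1e-7)
  expect_equal(back$bands$MIR, s$bands$MIR, tolerance = 1e-7)
  expect_equal(back$date, s$date)
  # explicit role -> file mapping must cover RED and NIR
  expect_error(read_scene(c(RED = paste0(stem, "_RED.asc"))), "NIR")
  expect_error(read_scene(file.path(dir, "nothere")), "no band files")
})

test_that("geographic CRS sidecars are rejected on read", {
  dir <- withr::local_tempdir()
  g <- geo_grid(3, 3, 30)
  p <- file.path(dir, "x.asc")
  write_asc(geo_raster(matrix(1, 3, 3), g), p)
  writeLines("EPSG:4326", file.path(dir, "x.prj"))
  expect_error(read_asc(p), "projected CRS")
})

test_that("scar catalogs round-trip through GeoJSON with attributes", {
  dir <- withr::local_tempdir()
  # 300 m square (9 ha) and a 100 m square with per-class attributes
  sq <- function(x0, y0, side)
    list(list(matrix(c(x0, y0, x0 + side, y0, x0 + side, y0 + side,
                       x0, y0 + side), ncol = 2, byrow = TRUE)))
  scars <- scar_set(list(sq(0, 0, 300), sq(1000, 0, 100)),
                    crs = "EPSG:32634", lc_312 = c(9, 0), lc_323 = c(0, 1))
  expect_equal(scars$area_ha, c(9, 1))
  p <- file.path(dir, "scars.geojson")
  write_scars(scars, p)
  back <- read_scars(p)
  expect_equal(nrow(back), 2)
  expect_equal(back$area_ha, c(9, 1), tolerance = 1e-9)
  expect_equal(back$lc_312, c(9, 0))
  expect_equal(back$lc_323, c(0, 1))
  expect_identical(attr(back, "crs"), "EPSG:32634")
  # empty catalog writes a valid empty layer
  p2 <- file.path(dir, "empty.geojson")
  write_scars(scar_set(list(), crs = "EPSG:32634"), p2)
  expect_equal(nrow(read_scars(p2)), 0)
})

test_that("disjoint polygon areas sum to the union area", {
  sq <- function(x0, y0, side)
    list(list(matrix(c(x0, y0, x0 + side, y0, x0 + side, y0 + side,
                       x0, y0 + side), ncol = 2, byrow = TRUE)))
  scars <- scar_set(list(sq(0, 0, 100), sq(500, 0, 200), sq(0, 500, 300)),
                    crs = "EPSG:32634")
  ov <- overlay_areas(scars, scars)
  expect_equal(sum(scars$area_ha), ov$dba_ha, tolerance = 1e-9)
  expect_equal(ov$fba_ha, 0)
})
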