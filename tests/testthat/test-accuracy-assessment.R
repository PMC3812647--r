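test_that("overlay splits identical, disjoint and offset polygon pairs", {
  id <- simulate_reference_pair(10, 0, 0)
  ov <- overlay_areas(id$detected, id$reference)
  expect_equal(unlist(ov), c(dba_ha = 10, fba_ha = 0, sba_ha = 0))
  dis <- simulate_reference_pair(0, 10, 10)
  ov2 <- overlay_areas(dis$detected, dis$reference)
  expect_equal(unlist(ov2), c(dba_ha = 0, fba_ha = 10, sba_ha = 10))
  # two 100 m squares offset by half a side: each part is 0.5 ha
  sq <- function(x0) list(list(matrix(c(x0, 0, x0 + 100, 0, x0 + 100, 100,
                                        x0, 100), ncol = 2, byrow = TRUE)))
  ov3 <- overlay_areas(scar_set(list(sq(0)), "EPSG:32634"),
                       scar_set(list(sq(50)), "EPSG:32634"))
  expect_equal(ov3$dba_ha, 0.5)
  expect_equal(ov3$fba_ha, 0.5)
  expect_equal(ov3$sba_ha, 0.5)
  # CRS mismatch refuses to overlay
  expect_error(overlay_areas(scar_set(list(sq(0)), "EPSG:32634"),
                             scar_set(list(sq(0)), "EPSG:2100")), "CRS")
})

test_that("donut holes are excluded from overlay areas", {
  outer <- matrix(c(0, 0, 300, 0, 300, 300, 0, 300), ncol = 2, byrow = TRUE)
  hole <- matrix(c(100, 100, 100, 200, 200, 200, 200, 100), ncol = 2,
                 byrow = TRUE)   # clockwise hole, 1 ha
  donut <- scar_set(list(list(list(outer, hole))), "EPSG:32634")
  expect_equal(donut$area_ha, 8)
  full <- scar_set(list(list(list(outer))), "EPSG:32634")
  ov <- overlay_areas(donut, full)
  expect_equal(ov$dba_ha, 8)
  expect_equal(ov$sba_ha, 1)   # the island counts only on the full layer
  expect_equal(ov$fba_ha, 0)
})

test_that("overlay identities hold for random rectangle pairs", {
  set.seed(77)
  for (i in 1:8) {
    d <- simulate_reference_pair(runif(1, 1, 50), runif(1, 0, 20),
                                 runif(1, 0, 20))
    ov <- overlay_areas(d$detected, d$reference)
    det_area <- sum(d$detected$area_ha)
    ref_area <- sum(d$reference$area_ha)
    expect_equal(ov$dba_ha + ov$fba_ha, det_area, tolerance = 1e-6)
    expect_equal(ov$dba_ha + ov$sba_ha, ref_area, tolerance = 1e-6)
    # swapping layers swaps false and skipped areas
    sw <- overlay_areas(d$reference, d$detected)
    expect_equal(sw$fba_ha, ov$sba_ha, tolerance = 1e-9)
    expect_equal(sw$sba_ha, ov$fba_ha, tolerance = 1e-9)
  }
})

test_that("accuracy metrics implement the validation formulas", {
  # external-validation identity: omission 466/5000 -> producer's 90.68%
  r <- accuracy_metrics(4534, 0, 466)
  expect_equal(r$producers_accuracy, 0.9068)
  expect_equal(r$omission_error, 0.0932)
  expect_equal(r$detected_area_efficiency, r$producers_accuracy)
  expect_equal(r$users_accuracy, 1)
  # the headline efficiency scale: dba 88, sba 12 -> 88%
  r2 <- accuracy_metrics(88, 6, 12)
  expect_equal(r2$detected_area_efficiency, 0.88)
  expect_equal(r2$commission_error, 6 / 94, tolerance = 1e-9)
  expect_equal(r2$omission_error, 0.12)
  # total-failure case
  r3 <- accuracy_metrics(0, 10, 10)
  expect_equal(r3$detected_area_efficiency, 0)
  expect_equal(r3$commission_error, 1)
  expect_equal(r3$omission_error, 1)
  expect_error(accuracy_metrics(-1, 0, 0), "non-negative")
})

test_that("undefined metrics are reported as NA, never 0", {
  r <- accuracy_metrics(0, 0, 10)       # nothing detected
  expect_true(is.na(r$commission_error))
  expect_true(is.na(r$users_accuracy))
  expect_equal(r$omission_error, 1)
  r2 <- accuracy_metrics(0, 10, 0)      # no reference burnt area
  expect_true(is.na(r2$detected_area_efficiency))
  expect_true(is.na(r2$producers_accuracy))
})

test_that("metric identities and bounds hold on random triples", {
  set.seed(3)
  for (i in 1:20) {
    v <- runif(3, 0, 100)
    r <- accuracy_metrics(v[1] + 0.1, v[2], v[3])
    expect_equal(r$detected_area_efficiency + r$omission_error, 1)
    expect_equal(r$producers_accuracy, 1 - r$omission_error)
    expect_equal(r$users_accuracy, 1 - r$commission_error)
    vals <- unlist(r[4:8])
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("tidiers expose the report as tibbles", {
  r <- accuracy_metrics(88, 6, 12)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  expect_equal(td$percent[td$metric == "detected_area_efficiency"], 88)
  gl <- glance(r)
  expect_equal(gl$dba_ha, 88)
})
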