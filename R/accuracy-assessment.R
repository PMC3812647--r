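#' Overlay detected against reference burn polygons
#'
#' Splits the two polygon unions into detected burnt area (DBA, common to
#' both), false burnt area (FBA, detected only) and skipped burnt area (SBA,
#' reference only). Interior rings ("donut" holes — unburnt islands inside a
#' scar) are excluded from both layers' areas. All geometry per layer is
#' pooled: multi-polygon events are validated as one union.
#'
#' @param detected,reference [scar_set()] catalogs (or bare lists of
#'   multipolygon geometries) in the same projected CRS.
#' @return A one-row tibble with `dba_ha`, `fba_ha`, `sba_ha`.
#' @examples
#' pair <- simulate_reference_pair(10, 0, 0)
#' overlay_areas(pair$detected, pair$reference)   # dba 10, fba 0, sba 0
#' @export
overlay_areas <- function(detected, reference) {
  get_geoms <- function(x) if (is.data.frame(x)) x$geometry else x
  get_crs <- function(x) if (is.data.frame(x)) scar_crs(x) else NA_character_
  crs_d <- get_crs(detected); crs_r <- get_crs(reference)
  if (!is.na(crs_d) && !is.na(crs_r) && !identical(crs_d, crs_r))
    stop("CRS mismatch between detected (", crs_d, ") and reference (",
         crs_r, ") layers")
  gd <- get_geoms(detected); gr <- get_geoms(reference)
  if (length(gd) == 0 && length(gr) == 0)
    return(tibble::tibble(dba_ha = 0, fba_ha = 0, sba_ha = 0))
  if (length(gd) == 0)
    return(tibble::tibble(dba_ha = 0, fba_ha = 0,
                          sba_ha = sum(vapply(gr, geom_area_m2, numeric(1))) / 1e4))
  if (length(gr) == 0)
    return(tibble::tibble(dba_ha = 0,
                          fba_ha = sum(vapply(gd, geom_area_m2, numeric(1))) / 1e4,
                          sba_ha = 0))
  cells <- overlay_cells(gd, gr)
  tibble::tibble(dba_ha = cells[["inter"]] / 1e4,
                 fba_ha = cells[["only_det"]] / 1e4,
                 sba_ha = cells[["only_ref"]] / 1e4)
}

#' Burned-area accuracy metrics from DBA/FBA/SBA
#'
#' Implements the area-based validation protocol:
#' detected-area efficiency `DBA/(DBA+SBA)` (identical to producer's
#' accuracy), commission error (false-area rate) `FBA/(DBA+FBA)`, omission
#' error (skipped-area rate) `SBA/(DBA+SBA)`, user's accuracy
#' `1 - commission`. Metrics whose denominator is zero are undefined and
#' reported as `NA`, never as 0.
#'
#' @param dba,fba,sba Hectares of detected, false and skipped burnt area,
#'   either as three numbers or a one-row data frame from [overlay_areas()]
#'   passed as `dba`.
#' @return An `accuracy_report` object (see [tidy.accuracy_report()]).
#' @examples
#' r <- accuracy_metrics(4534, 0, 466)
#' r$producers_accuracy   # 0.9068
#' @export
accuracy_metrics <- function(dba, fba = NULL, sba = NULL) {
  if (is.data.frame(dba)) {
    fba <- dba$fba_ha; sba <- dba$sba_ha; dba <- dba$dba_ha
  }
  if (any(c(dba, fba, sba) < 0)) stop("areas must be non-negative")
  eff <- if (dba + sba > 0) dba / (dba + sba) else NA_real_
  com <- if (dba + fba > 0) fba / (dba + fba) else NA_real_
  omi <- if (dba + sba > 0) sba / (dba + sba) else NA_real_
  structure(list(dba_ha = dba, fba_ha = fba, sba_ha = sba,
                 detected_area_efficiency = eff,
                 commission_error = com,
                 omission_error = omi,
                 producers_accuracy = if (is.na(omi)) NA_real_ else 1 - omi,
                 users_accuracy = if (is.na(com)) NA_real_ else 1 - com),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "n/a" else sprintf("%.2f%%", 100 * v)
  cat("Burned-area accuracy report\n",
      sprintf("  DBA %.2f ha, FBA %.2f ha, SBA %.2f ha\n",
              x$dba_ha, x$fba_ha, x$sba_ha),
      "  detected-area efficiency ", pct(x$detected_area_efficiency), "\n",
      "  commission error         ", pct(x$commission_error), "\n",
      "  omission error           ", pct(x$omission_error), "\n",
      "  producer's accuracy      ", pct(x$producers_accuracy), "\n",
      "  user's accuracy          ", pct(x$users_accuracy), "\n", sep = "")
  invisible(x)
}

#' Tidy burned-area accuracy reports
#'
#' `tidy()` returns one row per metric; `glance()` a one-row tibble with all
#' areas and metrics.
#'
#' @param x An `accuracy_report`.
#' @param ... Unused.
#' @method tidy accuracy_report
#' @export
tidy.accuracy_report <- function(x, ...) {
  metrics <- c("detected_area_efficiency", "commission_error",
               "omission_error", "producers_accuracy", "users_accuracy")
  est <- unname(vapply(metrics, function(m) x[[m]], numeric(1)))
  tibble::tibble(metric = metrics, estimate = est, percent = 100 * est)
}

#' @rdname tidy.accuracy_report
#' @method glance accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
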