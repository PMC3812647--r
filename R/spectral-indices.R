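#' Spectral burn indices
#'
#' The four biophysical indices the classification chain thresholds:
#'
#' * `nbr()` — Normalised Burn Ratio, (NIR - MIR)/(NIR + MIR). Falls sharply
#'   after fire as NIR reflectance drops and MIR rises.
#' * `ndvi()` — Normalised Difference Vegetation Index,
#'   (NIR - RED)/(NIR + RED); green-vegetation vigour.
#' * `ndvi_multi()` — multi-date NDVI, NDVI(pre) - NDVI(post); large positive
#'   values mark vegetation loss between the two dates.
#' * `albedo()` — broadband brightness proxy, (NIR + RED)/2; used to screen
#'   clouds and bright surfaces.
#'
#' All indices accept any linear radiometric unit: the normalised ratios are
#' unit-free and the albedo proxy scales linearly. Zero-denominator pixels
#' become nodata (`NA`) rather than a fabricated extreme value. Computation is
#' in double precision.
#'
#' @param scene An [ms_scene()] with the required bands.
#' @param pair A [scene_pair()] (for `ndvi_multi`).
#' @return A [geo_raster()] whose `name` records the index kind.
#' @examples
#' g <- geo_grid(1, 1, 30)
#' s <- ms_scene(list(RED = matrix(0.05), NIR = matrix(0.45),
#'                    MIR = matrix(0.18)), g, "2007-06-01")
#' nbr(s)$values      # (0.45 - 0.18)/(0.45 + 0.18)
#' ndvi(s)$values     # 0.8
#' albedo(s)$values   # 0.25
#' @name spectral_indices
NULL

#' @keywords internal
need_bands <- function(scene, roles, what) {
  miss <- setdiff(roles, names(scene$bands))
  if (length(miss))
    stop(what, " requires band(s) ", paste(miss, collapse = ", "),
         " not present in the scene")
}

#' @keywords internal
normalized_diff <- function(a, b) {
  den <- a + b
  out <- (a - b) / den
  out[den == 0] <- NA
  out
}

#' @rdname spectral_indices
#' @export
nbr <- function(scene) {
  need_bands(scene, c("NIR", "MIR"), "NBR")
  geo_raster(normalized_diff(scene$bands$NIR, scene$bands$MIR),
             scene$grid, "NBR")
}

#' @rdname spectral_indices
#' @export
ndvi <- function(scene) {
  need_bands(scene, c("NIR", "RED"), "NDVI")
  geo_raster(normalized_diff(scene$bands$NIR, scene$bands$RED),
             scene$grid, "NDVI")
}

#' @rdname spectral_indices
#' @export
ndvi_multi <- function(pair) {
  stopifnot(inherits(pair, "scene_pair"))
  geo_raster(ndvi(pair$pre)$values - ndvi(pair$post)$values,
             pair$pre$grid, "NDVI_MULTI")
}

#' @rdname spectral_indices
#' @export
albedo <- function(scene) {
  need_bands(scene, c("NIR", "RED"), "albedo")
  geo_raster((scene$bands$NIR + scene$bands$RED) / 2, scene$grid, "ALBEDO")
}
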