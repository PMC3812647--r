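#' Relative radiometric normalisation of a scene pair
#'
#' Maps the post-fire scene band-wise onto the radiometric scale of the
#' pre-fire scene so that multi-date differences reflect surface change, not
#' illumination or calibration drift.
#'
#' `method = "pif_linear"` (default) fits, per band, an ordinary least-squares
#' affine model `pre ~ gain * post + offset` over pseudo-invariant feature
#' (PIF) pixels: unmasked pixels in the lowest quartile of the raw
#' change-vector magnitude. The fit is iterated once — PIFs are re-selected
#' from the magnitude of the adjusted pair and the model refitted.
#' `method = "histogram_match"` matches each post band's empirical quantiles
#' onto the pre band's. `method = "none"` returns the pair unchanged.
#'
#' @param pair A [scene_pair()].
#' @param method One of `"pif_linear"`, `"histogram_match"`, `"none"`.
#' @param masks Optional [mask_stack()]; masked pixels are never PIFs.
#' @param min_pif Minimum PIF count required for a stable fit.
#' @return A [scene_pair()] whose post scene is transformed; the fitted
#'   per-band model is attached as attribute `"normalization_model"`, a
#'   tibble with columns `band`, `gain`, `offset`, `n_pif`, `residual_sd`.
#' @examples
#' sim <- simulate_scene_pair(geo_grid(40, 40, 30), burn_fraction = 0,
#'                            noise_sd = 0, seed = 1)
#' norm <- normalize_radiometry(sim$pair)
#' attr(norm, "normalization_model")   # gains ~1, offsets ~0
#' @export
normalize_radiometry <- function(pair,
                                 method = c("pif_linear", "histogram_match",
                                            "none"),
                                 masks = NULL, min_pif = 100) {
  stopifnot(inherits(pair, "scene_pair"))
  method <- match.arg(method)
  if (method == "none") return(pair)
  common <- intersect(names(pair$pre$bands), names(pair$post$bands))
  excl <- if (is.null(masks)) matrix(FALSE, pair$pre$grid$n_rows,
                                     pair$pre$grid$n_cols) else mask_any(masks)

  post_bands <- pair$post$bands
  if (method == "histogram_match") {
    model <- tibble::tibble(band = common, gain = NA_real_, offset = NA_real_,
                            n_pif = NA_integer_, residual_sd = NA_real_)
    for (b in common) {
      pre_v <- pair$pre$bands[[b]]; post_v <- post_bands[[b]]
      ok <- !excl & !is.na(pre_v) & !is.na(post_v)
      q <- stats::ecdf(post_v[ok])(post_v)
      matched <- stats::quantile(pre_v[ok], probs = pmin(pmax(q, 0), 1),
                                 names = FALSE, type = 7)
      out <- post_v
      out[!is.na(post_v)] <- matched[!is.na(post_v)]
      post_bands[[b]] <- out
    }
  } else {
    fit_on <- function(pif) {
      rows <- lapply(common, function(b) {
        x <- pair$post$bands[[b]][pif]
        y <- pair$pre$bands[[b]][pif]
        keep <- !is.na(x) & !is.na(y)
        x <- x[keep]; y <- y[keep]
        vx <- stats::var(x); vy <- stats::var(y)
        if (!is.finite(vx) || vx <= 1e-12) {
          # constant PIFs: the slope is underdetermined; a pure offset is
          # the only consistent model, and only if the target is constant too
          if (is.finite(vy) && vy > 1e-12)
            stop("degenerate zero-variance band ", b,
                 " among pseudo-invariant pixels")
          gain <- 1
          offset <- mean(y) - mean(x)
        } else {
          # reduced major-axis slope: symmetric in the two dates, so equal
          # measurement noise on both does not attenuate the gain toward 0
          # (ordinary regression of pre on noisy post would); identical to
          # the least-squares slope for noise-free affine pairs
          gain <- sqrt(vy / vx)
          offset <- mean(y) - gain * mean(x)
        }
        resid <- y - (gain * x + offset)
        tibble::tibble(band = b, gain = gain, offset = offset,
                       n_pif = length(x), residual_sd = stats::sd(resid))
      })
      dplyr::bind_rows(rows)
    }
    select_pif <- function(post_b) {
      diffs <- lapply(common, function(b) post_b[[b]] - pair$pre$bands[[b]])
      mag <- sqrt(Reduce(`+`, lapply(diffs, function(d) d^2)))
      cand <- !excl & !is.na(mag)
      if (sum(cand) < min_pif)
        stop("too few pseudo-invariant candidate pixels: ", sum(cand),
             " (need >= ", min_pif, ")")
      thr <- stats::quantile(mag[cand], 0.25, names = FALSE)
      pif <- cand & mag <= thr
      if (sum(pif) < min_pif) pif <- cand   # tiny scenes: use all candidates
      pif
    }
    model <- fit_on(select_pif(pair$post$bands))
    adj <- pair$post$bands
    for (i in seq_len(nrow(model)))
      adj[[model$band[i]]] <- model$gain[i] * adj[[model$band[i]]] + model$offset[i]
    model <- fit_on(select_pif(adj))                       # one re-selection pass
    if (any(!is.finite(model$gain)) || any(model$gain <= 0))
      stop("normalisation produced a non-positive gain; check inputs")
    for (i in seq_len(nrow(model))) {
      b <- model$band[i]
      post_bands[[b]] <- model$gain[i] * post_bands[[b]] + model$offset[i]
    }
  }
  out <- scene_pair(pair$pre,
                    ms_scene(post_bands, pair$post$grid, pair$post$date,
                             pair$post$sensor_id))
  attr(out, "normalization_model") <- if (method == "pif_linear") model else model
  out
}

#' Contaminant mask rules
#'
#' Threshold rules, on a reflectance-like scale, for the automatic
#' cloud/water/shadow screening:
#' cloud where albedo >= `cloud_albedo_min` and NDVI <= `cloud_ndvi_max`;
#' water where NDVI <= `water_ndvi_max` and NIR <= `water_nir_max`;
#' shadow where every available band <= `shadow_max`.
#' All values are overridable per sensor or landscape in the pipeline config.
#'
#' @param cloud_albedo_min,cloud_ndvi_max,water_ndvi_max,water_nir_max,shadow_max
#'   Rule thresholds.
#' @return A `mask_rules` list.
#' @export
mask_rules <- function(cloud_albedo_min = 0.35, cloud_ndvi_max = 0.10,
                       water_ndvi_max = 0.0, water_nir_max = 0.10,
                       shadow_max = 0.04) {
  structure(list(cloud_albedo_min = cloud_albedo_min,
                 cloud_ndvi_max = cloud_ndvi_max,
                 water_ndvi_max = water_ndvi_max,
                 water_nir_max = water_nir_max,
                 shadow_max = shadow_max),
            class = "mask_rules")
}

#' Build cloud / water / shadow / nodata masks for a scene
#'
#' Fully automatic rule-based screening using the scene's albedo, NDVI and
#' band values (see [mask_rules()]). Pixels with any nodata band are flagged
#' in the nodata mask. Masks may overlap.
#'
#' @param scene An [ms_scene()].
#' @param rules A [mask_rules()] object.
#' @return A [mask_stack()].
#' @export
build_masks <- function(scene, rules = mask_rules()) {
  stopifnot(inherits(scene, "ms_scene"))
  alb <- albedo(scene)$values
  nd <- ndvi(scene)$values
  nirv <- scene$bands$NIR
  nodata <- Reduce(`|`, lapply(scene$bands, is.na))
  cloud <- !nodata & !is.na(alb) & !is.na(nd) &
    alb >= rules$cloud_albedo_min & nd <= rules$cloud_ndvi_max
  water <- !nodata & !is.na(nd) & nd <= rules$water_ndvi_max &
    nirv <= rules$water_nir_max
  dark <- Reduce(`&`, lapply(scene$bands, function(b) !is.na(b) & b <= rules$shadow_max))
  shadow <- !nodata & dark
  mask_stack(scene$grid, cloud = cloud, water = water, shadow = shadow,
             nodata = nodata)
}

#' Radiometric change-vector magnitude
#'
#' Per-pixel Euclidean norm of the multiband difference (post - pre) over the
#' selected band roles. Symmetric under swapping the two dates.
#'
#' @param pair A [scene_pair()], normalised first unless deliberately raw.
#' @param bands Character vector of band roles (default RED/NIR/MIR,
#'   restricted to the roles present in both scenes).
#' @return A [geo_raster()] of magnitudes; `NA` where either scene is nodata.
#' @export
change_vector_magnitude <- function(pair, bands = NULL) {
  stopifnot(inherits(pair, "scene_pair"))
  common <- intersect(names(pair$pre$bands), names(pair$post$bands))
  if (is.null(bands)) bands <- intersect(c("RED", "NIR", "MIR"), common)
  if (length(bands) == 0) stop("empty band subset for change vectors")
  miss <- setdiff(bands, common)
  if (length(miss)) stop("band(s) not present in both scenes: ",
                         paste(miss, collapse = ", "))
  sq <- lapply(bands, function(b)
    (pair$post$bands[[b]] - pair$pre$bands[[b]])^2)
  geo_raster(sqrt(Reduce(`+`, sq)), pair$pre$grid, "change_magnitude")
}

#' Threshold a change magnitude into a change/no-change mask
#'
#' `method = "fixed"` flags pixels whose magnitude strictly exceeds `t`.
#' `method = "robust"` derives the threshold from the magnitude distribution
#' of unmasked pixels: `t = median + k * 1.4826 * MAD` (the 1.4826 factor
#' makes the median absolute deviation consistent with a Gaussian sigma),
#' so under no-change conditions roughly only k-sigma outliers are flagged.
#' The comparison is strict (`>`), so a constant field is never flagged.
#'
#' @param magnitude A [geo_raster()] from [change_vector_magnitude()].
#' @param method `"robust"` or `"fixed"`.
#' @param k Multiplier for the robust rule (default 3).
#' @param t Fixed threshold (required for `method = "fixed"`).
#' @param exclude Optional logical matrix of pixels to ignore when deriving
#'   the robust threshold (e.g. [mask_any()] output).
#' @return A `change_mask` object: list with logical `changed`, the
#'   `magnitude` raster and the `threshold` used.
#' @export
change_mask <- function(magnitude, method = c("robust", "fixed"), k = 3,
                        t = NULL, exclude = NULL) {
  stopifnot(inherits(magnitude, "geo_raster"))
  method <- match.arg(method)
  m <- magnitude$values
  ok <- !is.na(m)
  if (!is.null(exclude)) ok <- ok & !exclude
  if (!any(ok)) stop("all pixels are nodata or excluded; cannot threshold")
  if (method == "fixed") {
    if (is.null(t)) stop("fixed thresholding requires t")
    thr <- t
  } else {
    med <- stats::median(m[ok])
    mad_raw <- stats::mad(m[ok], constant = 1)
    thr <- med + k * 1.4826 * mad_raw
  }
  changed <- !is.na(m) & m > thr
  structure(list(changed = changed, magnitude = magnitude, threshold = thr),
            class = "change_mask")
}
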