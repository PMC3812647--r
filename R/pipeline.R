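#' Pipeline configuration
#'
#' Nested configuration for the full mapping chain, with one section per
#' stage. Unknown keys are rejected so a typo cannot silently fall back to a
#' default. Defaults (reflectance-like scale):
#'
#' * `normalize`: `method` "pif_linear" (also "histogram_match", "none").
#' * `masks`: the [mask_rules()] thresholds.
#' * `cva`: `bands` RED/NIR/MIR, `rule` "robust" with `k = 3` (or "fixed"
#'   with `t`).
#' * `classify`: the [threshold_config()] fields.
#' * `post`: `median_kernel` 3, `mmu_ha` 1, `connectivity` 8,
#'   `aggregate_gap_m` 0 (aggregation off).
#'
#' @param ... Named overrides as nested lists, e.g.
#'   `firescar_config(post = list(mmu_ha = 0.5))`.
#' @return A validated `firescar_config` list.
#' @export
firescar_config <- function(...) {
  defaults <- list(
    normalize = list(method = "pif_linear"),
    masks = list(cloud_albedo_min = 0.35, cloud_ndvi_max = 0.10,
                 water_ndvi_max = 0.0, water_nir_max = 0.10,
                 shadow_max = 0.04),
    cva = list(bands = c("RED", "NIR", "MIR"), rule = "robust", k = 3,
               t = NULL),
    classify = list(nbr_post_max = 0.0, dnvdi_min = 0.3, ndvi_post_max = 0.3,
                    albedo_post_min = NA, require_change = TRUE,
                    sensor_id = NA),
    post = list(median_kernel = 3, mmu_ha = 1.0, connectivity = 8,
                aggregate_gap_m = 0)
  )
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  # fail fast on invalid classification settings
  do.call(threshold_config, cfg$classify)
  if (!cfg$post$median_kernel %% 2)
    stop("post.median_kernel must be odd")
  if (!cfg$post$connectivity %in% c(4, 8))
    stop("post.connectivity must be 4 or 8")
  structure(cfg, class = "firescar_config")
}

#' @keywords internal
merge_config <- function(base, over, path) {
  if (length(over) == 0) return(base)
  bad <- setdiff(names(over), names(base))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], as.list(over[[nm]]),
                                 paste0(path, ".", nm))
    } else {
      base[nm] <- over[nm]      # keeps NULL assignments (e.g. cva$t)
    }
  }
  base
}

#' @rdname firescar_config
#' @param path Path to a YAML file whose top-level keys mirror the config
#'   sections.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(firescar_config, raw)
}

#' Run the full burn-scar mapping chain
#'
#' Executes, in order: radiometric normalisation, contaminant masking (both
#' dates; the exclusion masks are OR-ed), change-vector analysis and
#' change/no-change thresholding, spectral-index classification, median
#' filtering, minimum-mapping-unit enforcement, polygonization, event
#' aggregation and attribution. The per-stage summary records pixel and
#' polygon counts and total burnt hectares so area never silently grows
#' between the filtering stages.
#'
#' @param pre,post [ms_scene()] objects (or file stems readable by
#'   [read_scene()]).
#' @param config A [firescar_config()].
#' @param landcover Optional [geo_raster()] of land-cover classes for
#'   attribution.
#' @param out Optional path; when given, the scar catalog is written there
#'   as GeoJSON.
#' @return List with `scars` (a [scar_set()]), `burn` (final
#'   [burn_raster()]), `summary` (per-stage tibble), `masks`, `change`,
#'   `normalization_model` and the `config` used.
#' @export
run_pipeline <- function(pre, post, config = firescar_config(),
                         landcover = NULL, out = NULL) {
  stopifnot(inherits(config, "firescar_config"))
  if (is.character(pre)) pre <- read_scene(pre)
  if (is.character(post)) post <- read_scene(post)
  pair <- scene_pair(pre, post)
  px_ha <- pixel_area_ha(pair$pre$grid)

  stage_rows <- list()
  note <- function(stage, burnt_px, n_poly = NA_integer_) {
    stage_rows[[length(stage_rows) + 1]] <<-
      tibble::tibble(stage = stage, burnt_px = as.integer(burnt_px),
                     burnt_ha = burnt_px * px_ha, n_polygons = n_poly)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  masks_pre <- run_stage("masks", build_masks(pair$pre, do.call(mask_rules, config$masks)))
  masks_post <- run_stage("masks", build_masks(pair$post, do.call(mask_rules, config$masks)))
  masks <- mask_stack(pair$pre$grid,
                      cloud = masks_pre$cloud | masks_post$cloud,
                      water = masks_pre$water | masks_post$water,
                      shadow = masks_pre$shadow | masks_post$shadow,
                      nodata = masks_pre$nodata | masks_post$nodata)

  pair_n <- run_stage("normalize",
                      normalize_radiometry(pair, config$normalize$method,
                                           masks = masks))

  mag <- run_stage("cva", change_vector_magnitude(pair_n, config$cva$bands))
  change <- run_stage("cva", change_mask(mag,
                                         method = if (config$cva$rule == "fixed")
                                           "fixed" else "robust",
                                         k = config$cva$k, t = config$cva$t,
                                         exclude = mask_any(masks)))

  cfg_cls <- do.call(threshold_config, config$classify)
  burn <- run_stage("classify", classify_burnt(pair_n, cfg_cls, masks, change))
  note("classify", sum(burn$values))

  burn <- run_stage("median_filter",
                    median_filter(burn, config$post$median_kernel))
  note("median_filter", sum(burn$values))

  burn <- run_stage("mmu", remove_small_scars(burn, config$post$mmu_ha,
                                              config$post$connectivity))
  note("mmu", sum(burn$values))

  scars <- run_stage("polygonize", polygonize(burn, config$post$connectivity))
  note("polygonize", sum(burn$values), nrow(scars))

  if (config$post$aggregate_gap_m > 0 || nrow(scars) > 0)
    scars <- run_stage("aggregate",
                       aggregate_scars(scars, config$post$aggregate_gap_m))
  scars <- run_stage("attribute", attribute_scars(scars, landcover))
  note("attribute", sum(burn$values), nrow(scars))

  if (!is.null(out)) run_stage("write", write_scars(scars, out))

  list(scars = scars, burn = burn, summary = dplyr::bind_rows(stage_rows),
       masks = masks, change = change,
       normalization_model = attr(pair_n, "normalization_model"),
       config = config)
}
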