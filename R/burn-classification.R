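#' Index-threshold configuration for burnt/unburnt classification
#'
#' Each criterion is enabled by giving it a finite threshold and disabled with
#' `NA`. Inequalities are non-strict, in the direction the field name states:
#'
#' * `nbr_post_max` — burnt if post-fire NBR <= value (default 0.0);
#' * `dnvdi_min` — burnt if multi-date NDVI (pre - post) >= value (default 0.3);
#' * `ndvi_post_max` — burnt if post-fire NDVI <= value (default 0.3);
#' * `albedo_post_min` — burnt if post-fire albedo >= value (default disabled).
#'
#' Thresholds are sensor- and landscape-specific in operational use; these
#' defaults are on a reflectance-like scale and separate the synthetic
#' signature table cleanly. `require_change = TRUE` additionally demands the
#' change/no-change mask to flag the pixel, and criterion fusion is a
#' conjunction (AND): the conservative reading of comparing index thresholds
#' against the change map.
#'
#' @param nbr_post_max,dnvdi_min,ndvi_post_max,albedo_post_min Criterion
#'   thresholds; `NA` disables a criterion.
#' @param require_change Must the change mask also flag the pixel?
#' @param sensor_id Free-text tag for per-sensor profiles.
#' @return A `threshold_config` object.
#' @export
threshold_config <- function(nbr_post_max = 0.0, dnvdi_min = 0.3,
                             ndvi_post_max = 0.3, albedo_post_min = NA,
                             require_change = TRUE,
                             sensor_id = NA_character_) {
  vals <- c(nbr_post_max = nbr_post_max, dnvdi_min = dnvdi_min,
            ndvi_post_max = ndvi_post_max, albedo_post_min = albedo_post_min)
  if (all(is.na(vals))) stop("at least one classification criterion must be enabled")
  if (any(is.infinite(vals), na.rm = TRUE)) stop("thresholds must be finite")
  structure(list(nbr_post_max = nbr_post_max, dnvdi_min = dnvdi_min,
                 ndvi_post_max = ndvi_post_max,
                 albedo_post_min = albedo_post_min,
                 require_change = isTRUE(require_change),
                 sensor_id = sensor_id),
            class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  on <- function(v) if (is.na(v)) "off" else format(v)
  cat("<threshold_config nbr_post_max=", on(x$nbr_post_max),
      " dnvdi_min=", on(x$dnvdi_min),
      " ndvi_post_max=", on(x$ndvi_post_max),
      " albedo_post_min=", on(x$albedo_post_min),
      " require_change=", x$require_change, ">\n", sep = "")
  invisible(x)
}

#' Classify a scene pair into burnt / unburnt pixels
#'
#' Core processing: a pixel is burnt iff every enabled index criterion holds,
#' the change mask flags it (when `require_change`), and no contaminant mask
#' excludes it. Pixels where any needed index is nodata are unburnt. A
#' diagnostics matrix flagging low-confidence pixels — where the index
#' criteria and the change mask disagree — is attached as attribute
#' `"diagnostics"`.
#'
#' @param pair A [scene_pair()] (normalised upstream).
#' @param cfg A [threshold_config()].
#' @param masks Optional [mask_stack()] of contaminants.
#' @param change Optional [change_mask()]; required if `cfg$require_change`.
#' @return A [burn_raster()] with the config recorded as provenance.
#' @export
classify_burnt <- function(pair, cfg = threshold_config(), masks = NULL,
                           change = NULL) {
  stopifnot(inherits(pair, "scene_pair"), inherits(cfg, "threshold_config"))
  grid <- pair$pre$grid
  if (!is.null(masks) && !grids_equal(masks$grid, grid))
    stop("mask grid does not match the scene grid")
  if (cfg$require_change && is.null(change))
    stop("cfg requires the change mask but none was given")
  crit <- matrix(TRUE, grid$n_rows, grid$n_cols)
  apply_crit <- function(crit, values, thr, geq) {
    if (is.na(thr)) return(crit)
    ok <- if (geq) values >= thr else values <= thr
    ok[is.na(ok)] <- FALSE
    crit & ok
  }
  if (!is.na(cfg$nbr_post_max))
    crit <- apply_crit(crit, nbr(pair$post)$values, cfg$nbr_post_max, FALSE)
  if (!is.na(cfg$dnvdi_min))
    crit <- apply_crit(crit, ndvi_multi(pair)$values, cfg$dnvdi_min, TRUE)
  if (!is.na(cfg$ndvi_post_max))
    crit <- apply_crit(crit, ndvi(pair$post)$values, cfg$ndvi_post_max, FALSE)
  if (!is.na(cfg$albedo_post_min))
    crit <- apply_crit(crit, albedo(pair$post)$values, cfg$albedo_post_min, TRUE)

  burnt <- crit
  diag <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (!is.null(change)) {
    diag <- xor(crit, change$changed)
    if (cfg$require_change) burnt <- burnt & change$changed
  }
  if (!is.null(masks)) {
    excl <- mask_any(masks)
    burnt <- burnt & !excl
    diag <- diag & !excl
  }
  out <- burn_raster(burnt, grid, provenance = cfg)
  attr(out, "diagnostics") <- diag
  out
}

#' Calibrate index thresholds against labelled test sites
#'
#' Automated surrogate for supervised threshold selection by visual
#' inspection: an exhaustive grid search over candidate threshold values,
#' scored by the F1 of burnt-pixel detection over the labelled pixels. Ties
#' are broken toward the most conservative configuration — the one producing
#' the fewest burnt pixels over the whole scene.
#'
#' @param pair A [scene_pair()].
#' @param labeled_sites Data frame with columns `row`, `col` (1-based pixel
#'   indices) and `label` (`"burnt"` / `"unburnt"`); both labels required.
#' @param grid_spec Named list of candidate numeric vectors, names among
#'   `nbr_post_max`, `dnvdi_min`, `ndvi_post_max`, `albedo_post_min`.
#'   Criteria absent from `grid_spec` are disabled.
#' @param masks,change Optional [mask_stack()] / [change_mask()] applied
#'   during scoring.
#' @param require_change Passed through to the candidate configs.
#' @return The winning [threshold_config()], with attributes `"f1"` and
#'   `"search"` (tibble of every candidate and its score).
#' @export
calibrate_thresholds <- function(pair, labeled_sites, grid_spec,
                                 masks = NULL, change = NULL,
                                 require_change = FALSE) {
  stopifnot(is.data.frame(labeled_sites),
            all(c("row", "col", "label") %in% names(labeled_sites)))
  labs <- unique(labeled_sites$label)
  if (!all(c("burnt", "unburnt") %in% labs))
    stop("cannot calibrate: labelled sites must contain both burnt and ",
         "unburnt labels (got: ", paste(labs, collapse = ", "), ")")
  if (length(grid_spec) == 0 || any(lengths(grid_spec) == 0))
    stop("candidate grids must be non-empty")
  allowed <- c("nbr_post_max", "dnvdi_min", "ndvi_post_max", "albedo_post_min")
  bad <- setdiff(names(grid_spec), allowed)
  if (length(bad)) stop("unknown criteria in grid_spec: ",
                        paste(bad, collapse = ", "))

  combos <- expand.grid(grid_spec, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  idx <- cbind(labeled_sites$row, labeled_sites$col)
  truth <- labeled_sites$label == "burnt"

  score_one <- function(row) {
    args <- list(nbr_post_max = NA, dnvdi_min = NA, ndvi_post_max = NA,
                 albedo_post_min = NA, require_change = require_change)
    for (nm in names(row)) args[[nm]] <- row[[nm]]
    cfg <- do.call(threshold_config, args)
    br <- classify_burnt(pair, cfg, masks = masks, change = change)
    pred <- br$values[idx]
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    list(cfg = cfg, f1 = f1, n_burnt = sum(br$values))
  }
  results <- lapply(seq_len(nrow(combos)), function(i)
    score_one(as.list(combos[i, , drop = FALSE])))
  search <- tibble::as_tibble(combos)
  search$f1 <- vapply(results, `[[`, numeric(1), "f1")
  search$n_burnt <- vapply(results, function(r) as.numeric(r$n_burnt), numeric(1))
  ord <- order(-search$f1, search$n_burnt)
  best <- results[[ord[1]]]$cfg
  attr(best, "f1") <- search$f1[ord[1]]
  attr(best, "search") <- search
  best
}
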