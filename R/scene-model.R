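#' Georeferenced grid description
#'
#' Describes the raster grid every layer of the pipeline shares: a square-pixel
#' grid in a projected, metre-unit coordinate reference system, origin at the
#' upper-left pixel corner, rows increasing southwards (decreasing y).
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param pixel_size_m Side of a (square) pixel in metres.
#' @param origin_x,origin_y Projected coordinates of the upper-left corner of
#'   the grid.
#' @param crs Identifier of a projected, metre-unit CRS (e.g. `"EPSG:32634"`).
#'   Geographic (degree-unit) identifiers are rejected.
#' @return An object of class `geo_grid`.
#' @examples
#' g <- geo_grid(100, 100, 30)
#' pixel_area_ha(g)   # 0.09 ha for 30 m pixels
#' @export
geo_grid <- function(n_rows, n_cols, pixel_size_m,
                     origin_x = 0, origin_y = n_rows * pixel_size_m,
                     crs = "EPSG:32634") {
  stopifnot(n_rows >= 1, n_cols >= 1, pixel_size_m > 0)
  if (!is_projected_crs(crs))
    stop("projected CRS required: '", crs,
         "' looks geographic (degree units); reproject inputs first")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_size_m = as.numeric(pixel_size_m),
                 origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
                 crs = crs),
            class = "geo_grid")
}

#' @export
format.geo_grid <- function(x, ...) {
  sprintf("<geo_grid %d x %d @ %g m, origin (%g, %g), %s>",
          x$n_rows, x$n_cols, x$pixel_size_m, x$origin_x, x$origin_y, x$crs)
}

#' @export
print.geo_grid <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @rdname geo_grid
#' @export
pixel_area_ha <- function(grid) grid$pixel_size_m^2 / 1e4

# Heuristic check that a CRS identifier denotes a projected, metre-unit CRS.
# Recognises the common geographic identifiers; everything else is assumed
# projected (the package treats CRS ids as opaque labels otherwise).
#' @keywords internal
is_projected_crs <- function(crs) {
  if (is.null(crs) || is.na(crs) || !nzchar(crs)) return(FALSE)
  !grepl("4326|4269|4258|CRS84|longlat|lonlat|degree", crs, ignore.case = TRUE)
}

#' @keywords internal
grids_equal <- function(a, b, tol = 1e-6) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$pixel_size_m - b$pixel_size_m) < tol &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    identical(a$crs, b$crs)
}

#' Single-band georeferenced raster
#'
#' A matrix of values plus its [geo_grid()]. Used for DEMs, land-cover class
#' rasters, index rasters and change magnitudes. `NA` encodes nodata.
#'
#' @param values Numeric (or integer) matrix, `grid$n_rows` x `grid$n_cols`.
#' @param grid A [geo_grid()].
#' @param name Layer name (free text).
#' @return An object of class `geo_raster`.
#' @export
geo_raster <- function(values, grid, name = "layer") {
  stopifnot(inherits(grid, "geo_grid"), is.matrix(values))
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("raster dimensions do not match grid (",
         nrow(values), "x", ncol(values), " vs ",
         grid$n_rows, "x", grid$n_cols, ")")
  structure(list(values = values, grid = grid, name = name),
            class = "geo_raster")
}

#' @export
print.geo_raster <- function(x, ...) {
  cat("<geo_raster '", x$name, "' ", format(x$grid), ">\n", sep = "")
  invisible(x)
}

#' Multispectral scene
#'
#' A stack of co-registered single-band rasters labelled by spectral role.
#' RED and NIR are always required; MIR is required by the Normalised Burn
#' Ratio. Band values are any linear radiometric unit (radiance, reflectance
#' or digital numbers): every index in the chain is a ratio or an average, so
#' the unit cancels or scales out. `NA` encodes nodata.
#'
#' @param bands Named list of numeric matrices; names among
#'   `RED, NIR, MIR, GREEN, BLUE`.
#' @param grid A [geo_grid()].
#' @param date Acquisition date (`Date` or coercible string).
#' @param sensor_id Free-text sensor tag.
#' @param nodata_value Optional sentinel; matching values are converted to `NA`.
#' @return An object of class `ms_scene`.
#' @export
ms_scene <- function(bands, grid, date, sensor_id = NA_character_,
                     nodata_value = NULL) {
  stopifnot(inherits(grid, "geo_grid"), is.list(bands))
  roles <- names(bands)
  allowed <- c("RED", "NIR", "MIR", "GREEN", "BLUE")
  if (is.null(roles) || !all(roles %in% allowed))
    stop("band roles must be among ", paste(allowed, collapse = ", "))
  if (!all(c("RED", "NIR") %in% roles))
    stop("bands RED and NIR are required (got: ",
         paste(roles, collapse = ", "), ")")
  dims <- c(grid$n_rows, grid$n_cols)
  for (r in roles) {
    m <- bands[[r]]
    if (!is.matrix(m) || !all(dim(m) == dims))
      stop("band ", r, " does not match the grid dimensions")
    if (!is.null(nodata_value)) m[m == nodata_value] <- NA
    if (any(!is.finite(m) & !is.na(m)))
      stop("band ", r, " contains non-finite values that are not nodata")
    bands[[r]] <- m
  }
  structure(list(grid = grid, bands = bands, date = as.Date(date),
                 sensor_id = sensor_id),
            class = "ms_scene")
}

#' @export
print.ms_scene <- function(x, ...) {
  cat("<ms_scene [", paste(names(x$bands), collapse = ","), "] ",
      format(x$date), " ", format(x$grid), ">\n", sep = "")
  invisible(x)
}

#' Pre/post-fire scene pair
#'
#' Two co-registered [ms_scene()]s on an identical grid with strictly
#' increasing acquisition dates.
#'
#' @param pre,post [ms_scene()] objects.
#' @return An object of class `scene_pair`.
#' @export
scene_pair <- function(pre, post) {
  stopifnot(inherits(pre, "ms_scene"), inherits(post, "ms_scene"))
  if (!grids_equal(pre$grid, post$grid))
    stop("pre and post scenes are not co-registered (grids differ)")
  if (!(pre$date < post$date))
    stop("pre-fire date (", pre$date, ") must precede post-fire date (",
         post$date, ")")
  structure(list(pre = pre, post = post), class = "scene_pair")
}

#' Cloud / water / shadow / nodata mask stack
#'
#' Boolean exclusion masks on the shared grid. Masks may overlap; the
#' combined exclusion mask is their elementwise OR.
#'
#' @param grid A [geo_grid()].
#' @param cloud,water,shadow,nodata Logical matrices (default all-`FALSE`).
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(grid, cloud = NULL, water = NULL, shadow = NULL,
                       nodata = NULL) {
  stopifnot(inherits(grid, "geo_grid"))
  dims <- c(grid$n_rows, grid$n_cols)
  blank <- matrix(FALSE, dims[1], dims[2])
  fix <- function(m, nm) {
    if (is.null(m)) return(blank)
    if (!is.matrix(m) || !all(dim(m) == dims))
      stop("mask ", nm, " does not match the grid")
    m & !is.na(m)
  }
  structure(list(cloud = fix(cloud, "cloud"), water = fix(water, "water"),
                 shadow = fix(shadow, "shadow"), nodata = fix(nodata, "nodata"),
                 grid = grid),
            class = "mask_stack")
}

#' @rdname mask_stack
#' @param masks A `mask_stack`.
#' @return `mask_any()`: logical matrix, TRUE where any mask excludes a pixel.
#' @export
mask_any <- function(masks) {
  stopifnot(inherits(masks, "mask_stack"))
  masks$cloud | masks$water | masks$shadow | masks$nodata
}

# ---- burn raster ----------------------------------------------------------

#' Burnt/unburnt raster
#'
#' @param values Logical matrix (`TRUE` = burnt).
#' @param grid A [geo_grid()].
#' @param provenance Optional [threshold_config()] recorded for traceability.
#' @return An object of class `burn_raster`.
#' @export
burn_raster <- function(values, grid, provenance = NULL) {
  stopifnot(inherits(grid, "geo_grid"), is.matrix(values), is.logical(values))
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("burn raster dimensions do not match grid")
  values[is.na(values)] <- FALSE
  structure(list(values = values, grid = grid, provenance = provenance),
            class = "burn_raster")
}

#' @export
print.burn_raster <- function(x, ...) {
  cat("<burn_raster ", sum(x$values), " burnt px, ", format(x$grid), ">\n",
      sep = "")
  invisible(x)
}

# ---- scar catalog ---------------------------------------------------------

#' Burn-scar catalog
#'
#' A tibble with one row per scar feature: `scar_id`, `event_id`, `area_ha`
#' and a `geometry` list-column (multipolygon: list of polygons, each a list
#' of rings, each ring an n x 2 coordinate matrix; ring 1 is the exterior,
#' later rings are holes). Hole area is excluded from `area_ha`. The CRS id
#' travels as the `crs` attribute.
#'
#' @param geometry List of multipolygon geometries.
#' @param crs CRS identifier shared by all geometries.
#' @param event_id Optional event identifiers (default: one per scar).
#' @param ... Additional per-scar attribute columns (recycled by tibble rules).
#' @return A `scar_set` tibble.
#' @export
scar_set <- function(geometry, crs, event_id = NULL, ...) {
  n <- length(geometry)
  area_ha <- vapply(geometry, function(g) geom_area_m2(g) / 1e4, numeric(1))
  out <- tibble::tibble(scar_id = seq_len(n),
                        event_id = if (is.null(event_id)) seq_len(n) else event_id,
                        area_ha = area_ha,
                        geometry = geometry, ...)
  attr(out, "crs") <- crs
  class(out) <- c("scar_set", class(out))
  out
}

#' @keywords internal
scar_crs <- function(scars) attr(scars, "crs") %||% NA_character_

#' @export
print.scar_set <- function(x, ...) {
  cat("# Burn-scar catalog (", nrow(x), " scars, ",
      length(unique(x$event_id)), " events, ",
      format(sum(x$area_ha), big.mark = ","), " ha, CRS ",
      scar_crs(x), ")\n", sep = "")
  NextMethod()
}

# ---- ESRI ASCII grid I/O --------------------------------------------------

#' Read / write single-band rasters as ESRI ASCII grids
#'
#' Plain-text `.asc` rasters readable by standard GIS software. The CRS
#' identifier is carried in a `.prj` sidecar file holding the id string.
#'
#' @param x A [geo_raster()].
#' @param path Output `.asc` path (`write_asc`) or input path (`read_asc`).
#' @param nodata Sentinel written for `NA` cells.
#' @param crs CRS id used when no `.prj` sidecar exists.
#' @return `read_asc()` returns a [geo_raster()].
#' @export
write_asc <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "geo_raster"))
  g <- x$grid
  hdr <- c(paste("ncols", g$n_cols), paste("nrows", g$n_rows),
           paste("xllcorner", format(g$origin_x, digits = 15)),
           paste("yllcorner", format(g$origin_y - g$n_rows * g$pixel_size_m,
                                     digits = 15)),
           paste("cellsize", format(g$pixel_size_m, digits = 15)),
           paste("NODATA_value", nodata))
  v <- x$values
  v[is.na(v)] <- nodata
  lines <- apply(v, 1, function(row) paste(format(row, digits = 9, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " "))
  writeLines(c(hdr, lines), path)
  writeLines(g$crs, sub("\\.asc$", ".prj", path))
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path, crs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  prj <- sub("\\.asc$", ".prj", path)
  if (is.null(crs)) crs <- if (file.exists(prj)) readLines(prj)[1] else "EPSG:32634"
  nr <- hdr$nrows; nc <- hdr$ncols
  grid <- geo_grid(nr, nc, hdr$cellsize,
                   origin_x = hdr$xllcorner,
                   origin_y = hdr$yllcorner + nr * hdr$cellsize,
                   crs = crs)
  geo_raster(vals, grid, name = sub("\\.asc$", "", basename(path)))
}

#' Read / write multispectral scenes
#'
#' A scene is stored as one ESRI ASCII grid per band named
#' `<stem>_<ROLE>.asc`, a `<stem>.prj` CRS sidecar and a `<stem>.json`
#' metadata sidecar (acquisition date, sensor). Only projected, metre-unit
#' CRSs are accepted; geographic rasters must be reprojected upstream.
#'
#' @param path File stem (`write_scene`) or stem / named character vector of
#'   role -> `.asc` paths (`read_scene`).
#' @param scene An [ms_scene()].
#' @param band_map For `read_scene` with a stem: character vector of roles to
#'   read (default: all of RED/NIR/MIR/GREEN/BLUE that exist on disk).
#' @param date,sensor_id Overrides for the metadata sidecar.
#' @return `read_scene()` returns an [ms_scene()].
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "ms_scene"))
  for (r in names(scene$bands))
    write_asc(geo_raster(scene$bands[[r]], scene$grid, r),
              paste0(path, "_", r, ".asc"))
  writeLines(scene$grid$crs, paste0(path, ".prj"))
  jsonlite::write_json(list(date = format(scene$date),
                            sensor_id = scene$sensor_id,
                            bands = names(scene$bands)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path, band_map = NULL, date = NULL,
                       sensor_id = NULL) {
  if (is.null(names(path))) {
    stem <- path
    roles <- band_map %||% c("RED", "NIR", "MIR", "GREEN", "BLUE")
    files <- stats::setNames(paste0(stem, "_", roles, ".asc"), roles)
    files <- files[file.exists(files)]
    meta_path <- paste0(stem, ".json")
  } else {
    files <- path
    meta_path <- NULL
  }
  if (length(files) == 0) stop("no band files found for: ", path[1])
  if (!all(c("RED", "NIR") %in% names(files)))
    stop("band map must cover at least RED and NIR (got: ",
         paste(names(files), collapse = ", "), ")")
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("missing band file(s): ",
                            paste(missing, collapse = ", "))
  rasters <- lapply(files, read_asc)
  grid <- rasters[[1]]$grid
  meta <- if (!is.null(meta_path) && file.exists(meta_path))
    jsonlite::read_json(meta_path) else list()
  ms_scene(lapply(rasters, `[[`, "values"), grid,
           date = date %||% meta$date %||% Sys.Date(),
           sensor_id = sensor_id %||% meta$sensor_id %||% NA_character_)
}

# ---- GeoJSON scar I/O -----------------------------------------------------

# Close a ring for GeoJSON (repeat first vertex) as a list of [x, y] pairs.
#' @keywords internal
ring_to_json <- function(ring) {
  closed <- rbind(ring, ring[1, , drop = FALSE])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

#' Write / read burn-scar catalogs as GeoJSON
#'
#' Features are MultiPolygons in the catalog's projected CRS (recorded in a
#' foreign `crs` member, as commonly done for non-WGS84 GeoJSON). All
#' non-geometry columns become feature properties; an empty catalog writes a
#' valid empty FeatureCollection.
#'
#' @param scars A [scar_set()] tibble.
#' @param path Output (`write_scars`) or input (`read_scars`) `.geojson` path.
#' @return `read_scars()` returns a [scar_set()] tibble.
#' @export
write_scars <- function(scars, path) {
  props_cols <- setdiff(names(scars), "geometry")
  features <- lapply(seq_len(nrow(scars)), function(i) {
    geom <- scars$geometry[[i]]
    coords <- lapply(geom, function(poly) lapply(poly, ring_to_json))
    props <- lapply(scars[i, props_cols, drop = FALSE], function(col) {
      v <- if (is.list(col)) col[[1]] else col[[1]]
      v
    })
    names(props) <- props_cols
    list(type = "Feature",
         geometry = list(type = "MultiPolygon", coordinates = coords),
         properties = props)
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = scar_crs(scars))),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scars
#' @export
read_scars <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fc <- jsonlite::read_json(path)
  crs <- tryCatch(fc$crs$properties$name, error = function(e) NA_character_)
  feats <- fc$features
  if (length(feats) == 0)
    return(scar_set(list(), crs = crs %||% NA_character_))
  parse_ring <- function(rj) {
    m <- do.call(rbind, lapply(rj, function(p) c(p[[1]], p[[2]])))
    # drop the closing vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  geoms <- lapply(feats, function(f) {
    g <- f$geometry
    if (g$type == "Polygon") {
      list(lapply(g$coordinates, parse_ring))
    } else if (g$type == "MultiPolygon") {
      lapply(g$coordinates, function(poly) lapply(poly, parse_ring))
    } else stop("unsupported geometry type: ", g$type)
  })
  prop_names <- unique(unlist(lapply(feats, function(f) names(f$properties))))
  props <- lapply(stats::setNames(prop_names, prop_names), function(nm)
    vapply(feats, function(f) {
      v <- f$properties[[nm]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1)))
  extra <- props[setdiff(prop_names, c("scar_id", "event_id", "area_ha"))]
  out <- do.call(scar_set,
                 c(list(geometry = geoms, crs = crs %||% NA_character_,
                        event_id = if ("event_id" %in% prop_names)
                          as.integer(props$event_id) else NULL),
                   extra))
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
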