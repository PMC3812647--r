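# Seedable synthetic fixtures: scene pairs with known burn truth,
# contaminants and noise; exact-overlap polygon pairs; DEM/land-cover
# rasters. All generators are pure functions of (parameters, seed).

#' Spectral signature table for synthetic surfaces
#'
#' Mean RED/NIR/MIR values (reflectance-like scale) per surface type. Chosen
#' so the default mask rules and classification thresholds separate the
#' classes by construction: healthy vegetation has high NDVI (0.8) and NBR
#' (0.43); the burnt signature drops NIR and raises MIR (NBR -0.43, NDVI
#' 0.2, multi-date NDVI 0.6); water is dark with negative NDVI; cloud is
#' bright with near-zero NDVI.
#'
#' @return Tibble with columns `surface`, `red`, `nir`, `mir`.
#' @export
signature_table <- function() {
  tibble::tribble(
    ~surface,      ~red, ~nir, ~mir,
    "healthy_veg", 0.05, 0.45, 0.18,
    "burnt",       0.08, 0.12, 0.30,
    "water",       0.04, 0.02, 0.01,
    "cloud",       0.40, 0.42, 0.38,
    "bare_soil",   0.18, 0.25, 0.22
  )
}

# Contiguous irregular blob of exactly `target_px` pixels within `avail`.
# Union of discs along a short random walk, morphological 3x3 closing, then
# trimmed/grown to the exact pixel count (growth keeps contiguity).
#' @keywords internal
grow_blob <- function(avail, target_px) {
  nr <- nrow(avail); nc <- ncol(avail)
  if (target_px <= 0) return(matrix(FALSE, nr, nc))
  open_idx <- which(avail)
  if (length(open_idx) < target_px)
    stop("infeasible blob packing: ", target_px,
         " pixels requested but only ", length(open_idx), " available")
  start <- open_idx[sample.int(length(open_idx), 1)]
  sr <- ((start - 1) %% nr) + 1; sc <- ((start - 1) %/% nr) + 1
  n_steps <- 10L
  r <- max(1.5, sqrt(target_px / (pi * n_steps)) * 1.6)
  blob <- matrix(FALSE, nr, nc)
  cx <- sc; cy <- sr
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (s in seq_len(n_steps)) {
    rad <- r * stats::runif(1, 0.7, 1.3)
    blob <- blob | ((rows - cy)^2 + (cols - cx)^2 <= rad^2)
    ang <- stats::runif(1, 0, 2 * pi)
    step <- r * stats::runif(1, 0.5, 1.2)
    cy <- min(max(cy + sin(ang) * step, 1), nr)
    cx <- min(max(cx + cos(ang) * step, 1), nc)
  }
  blob <- blob & avail
  blob <- morpho_close(blob) & avail
  # exact pixel count: trim fringe (farthest from centroid) or grow frontier
  count <- sum(blob)
  if (count > target_px) {
    idx <- which(blob)
    br <- ((idx - 1) %% nr) + 1; bc <- ((idx - 1) %/% nr) + 1
    d <- (br - mean(br))^2 + (bc - mean(bc))^2
    blob[idx[order(d, decreasing = TRUE)[seq_len(count - target_px)]]] <- FALSE
    lab <- label_components(blob, 8)
    if (max(lab) > 1) {
      main <- which.max(tabulate(lab[lab > 0]))
      blob <- lab == main
    }
  }
  while (sum(blob) < target_px) {
    frontier <- which(dilate4(blob) & !blob & avail)
    if (length(frontier) == 0)
      stop("infeasible blob packing: cannot reach target size")
    take <- min(length(frontier), target_px - sum(blob))
    blob[sample(frontier, take)] <- TRUE
  }
  blob
}

#' @keywords internal
shift_or <- function(m, shifts) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
    ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
    out[ok_r, ok_c] <- out[ok_r, ok_c] | m[src_r[ok_r], src_c[ok_c]]
  }
  out
}

#' @keywords internal
dilate4 <- function(m) shift_or(m, list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))

#' @keywords internal
dilate8 <- function(m) {
  shift_or(m, list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
}

#' @keywords internal
morpho_close <- function(m) !dilate8(!dilate8(m))

#' Simulate a pre/post-fire scene pair with known truth
#'
#' Pre-fire scene: healthy vegetated background (optionally with water
#' bodies). Post-fire scene: the same background with the burnt signature
#' inside `n_scars` contiguous irregular blobs totalling exactly
#' `round(burn_fraction * n_pixels)` pixels. Clouds are placed independently
#' in each scene; Gaussian noise (sd `noise_sd`, clipped at 0) is added per
#' band. Identical seeds give bit-identical output.
#'
#' @param grid A [geo_grid()] (default 200 x 200 at 30 m).
#' @param burn_fraction Target burnt proportion of the grid, in [0, 0.5].
#' @param n_scars Number of distinct scars.
#' @param contaminants List with `cloud_fraction` and `water_fraction`
#'   proportions (defaults 0).
#' @param noise_sd Per-band additive Gaussian noise sd (reflectance units).
#' @param seed Integer seed; required — generation has no hidden entropy.
#' @return List with `pair` (a [scene_pair()]) and `truth`: the truth
#'   [burn_raster()], truth `scars` catalog, contaminant masks
#'   (`cloud_pre`, `cloud_post`, `water`) and the generation `params`.
#' @export
simulate_scene_pair <- function(grid = geo_grid(200, 200, 30),
                                burn_fraction = 0.1, n_scars = 3,
                                contaminants = list(cloud_fraction = 0,
                                                    water_fraction = 0),
                                noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(burn_fraction >= 0, burn_fraction < 1)
  if (burn_fraction > 0.5)
    stop("infeasible blob packing: burn_fraction ", burn_fraction,
         " too high for non-overlapping scars")
  set.seed(seed)
  nr <- grid$n_rows; nc <- grid$n_cols
  npix <- nr * nc
  sig <- signature_table()
  sig_of <- function(sfc) unlist(sig[sig$surface == sfc, c("red", "nir", "mir")])

  cloud_fr <- contaminants$cloud_fraction %||% 0
  water_fr <- contaminants$water_fraction %||% 0

  water <- matrix(FALSE, nr, nc)
  if (water_fr > 0)
    water <- grow_blob(!water, round(water_fr * npix))

  burn <- matrix(FALSE, nr, nc)
  target_total <- round(burn_fraction * npix)
  if (target_total > 0 && n_scars > 0) {
    per <- diff(round(seq(0, target_total, length.out = n_scars + 1)))
    for (k in seq_len(n_scars)) {
      # keep scars separated so they stay distinct components
      avail <- !water & !dilate8(dilate8(burn))
      burn <- burn | grow_blob(avail, per[k])
    }
  }

  cloud_pre <- cloud_post <- matrix(FALSE, nr, nc)
  if (cloud_fr > 0) {
    cloud_pre <- grow_blob(matrix(TRUE, nr, nc), round(cloud_fr * npix))
    cloud_post <- grow_blob(matrix(TRUE, nr, nc), round(cloud_fr * npix))
  }

  compose <- function(burnt_on, cloud) {
    bands <- list()
    for (b in c("red", "nir", "mir")) {
      m <- matrix(sig_of("healthy_veg")[[b]], nr, nc)
      if (burnt_on) m[burn] <- sig_of("burnt")[[b]]
      m[water] <- sig_of("water")[[b]]
      m[cloud] <- sig_of("cloud")[[b]]
      if (noise_sd > 0) m <- pmax(m + stats::rnorm(npix, 0, noise_sd), 0)
      bands[[toupper(b)]] <- m
    }
    names(bands) <- c("RED", "NIR", "MIR")
    bands
  }
  pre <- ms_scene(compose(FALSE, cloud_pre), grid, "2007-06-15", "synthetic")
  post <- ms_scene(compose(TRUE, cloud_post), grid, "2007-09-15", "synthetic")
  truth_burn <- burn_raster(burn, grid)
  list(pair = scene_pair(pre, post),
       truth = list(burn = truth_burn,
                    scars = polygonize(truth_burn),
                    cloud_pre = cloud_pre, cloud_post = cloud_post,
                    water = water,
                    params = list(burn_fraction = burn_fraction,
                                  n_scars = n_scars,
                                  contaminants = contaminants,
                                  noise_sd = noise_sd, seed = seed)))
}

#' Construct detected/reference polygon pairs with exact overlay areas
#'
#' Builds axis-aligned rectangles whose overlay yields exactly the requested
#' detected (DBA), false (FBA) and skipped (SBA) burnt areas, for exercising
#' the validation protocol.
#'
#' @param dba_ha,fba_ha,sba_ha Requested areas in hectares (all >= 0, not
#'   all zero).
#' @param crs CRS id given to both layers.
#' @return List with `detected` and `reference` [scar_set()] catalogs.
#' @examples
#' p <- simulate_reference_pair(88, 6, 12)
#' accuracy_metrics(overlay_areas(p$detected, p$reference))
#' @export
simulate_reference_pair <- function(dba_ha, fba_ha = 0, sba_ha = 0,
                                    crs = "EPSG:32634") {
  stopifnot(dba_ha >= 0, fba_ha >= 0, sba_ha >= 0)
  if (dba_ha + fba_ha + sba_ha == 0)
    stop("at least one of dba, fba, sba must be positive")
  h <- 100                       # strip height in metres; 1 ha per 100 m run
  len <- function(ha) ha * 1e4 / h
  ref <- list(); det <- list()
  if (dba_ha + sba_ha > 0)
    ref <- list(rect_geom(0, 0, len(sba_ha + dba_ha), h))
  if (dba_ha > 0) {
    det <- list(rect_geom(len(sba_ha), 0, len(sba_ha + dba_ha + fba_ha), h))
  } else if (fba_ha > 0) {
    det <- list(rect_geom(0, 2 * h, len(fba_ha), 3 * h))   # disjoint strip
  }
  list(detected = scar_set(det, crs = crs),
       reference = scar_set(ref, crs = crs))
}

# Smooth Gaussian random field via two box-blur passes (reflect padding).
#' @keywords internal
smooth_field <- function(nr, nc, k = 7L) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  h <- k %/% 2L
  blur <- function(m) {
    ri <- reflect_index(seq(1 - h, nr + h), nr)
    ci <- reflect_index(seq(1 - h, nc + h), nc)
    p <- m[ri, ci, drop = FALSE]
    acc <- matrix(0, nr, nc)
    for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L))
      acc <- acc + p[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
    acc / k^2
  }
  blur(blur(f))
}

#' Simulate a DEM and a categorical land-cover raster
#'
#' Spatially coherent rasters with requested per-zone / per-class pixel
#' shares (exact up to rounding of cumulative counts, i.e. +-1 pixel).
#' Elevations are spread linearly within each zone; the open top zone spans
#' 500 m above its lower edge.
#'
#' @param grid A [geo_grid()].
#' @param zone_shares Shares per elevation zone, summing to 1.
#' @param zone_edges Ascending zone edges in metres
#'   (default `c(0, 500, 1000, 1500, Inf)`).
#' @param classes Named numeric vector of land-cover class shares (names are
#'   integer class codes), summing to 1.
#' @param seed Integer seed.
#' @return List with `dem` and `landcover` [geo_raster()]s.
#' @export
simulate_terrain <- function(grid, zone_shares = c(0.65, 0.25, 0.08, 0.02),
                             zone_edges = c(0, 500, 1000, 1500, Inf),
                             classes = c("312" = 0.5, "323" = 0.5), seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(abs(sum(zone_shares) - 1) < 1e-9, abs(sum(classes) - 1) < 1e-9,
            length(zone_shares) == length(zone_edges) - 1)
  if (length(classes) == 0) stop("empty class mix")
  set.seed(seed)
  nr <- grid$n_rows; nc <- grid$n_cols
  npix <- nr * nc

  alloc <- function(shares) {
    cuts <- round(cumsum(shares) * npix)
    diff(c(0, cuts))
  }
  # DEM: rank a smooth field, fill zones in elevation order
  field <- smooth_field(nr, nc)
  ord <- order(field)
  dem <- numeric(npix)
  counts <- alloc(zone_shares)
  pos <- 0
  for (z in seq_along(counts)) {
    if (counts[z] == 0) next
    lo <- zone_edges[z]
    hi <- if (is.infinite(zone_edges[z + 1])) lo + 500 else zone_edges[z + 1]
    # spread linearly inside the zone, strictly below the upper edge
    dem[ord[pos + seq_len(counts[z])]] <-
      lo + (seq_len(counts[z]) - 1) / counts[z] * (hi - lo)
    pos <- pos + counts[z]
  }
  dem <- matrix(dem, nr, nc)

  field2 <- smooth_field(nr, nc)
  ord2 <- order(field2)
  lc <- integer(npix)
  counts2 <- alloc(classes)
  codes <- as.integer(names(classes))
  pos <- 0
  for (k in seq_along(counts2)) {
    if (counts2[k] == 0) next
    lc[ord2[pos + seq_len(counts2[k])]] <- codes[k]
    pos <- pos + counts2[k]
  }
  lc <- matrix(lc, nr, nc)
  list(dem = geo_raster(dem, grid, "dem"),
       landcover = geo_raster(lc, grid, "landcover"))
}
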