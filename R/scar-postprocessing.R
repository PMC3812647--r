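# Post-processing: salt-and-pepper filtering, minimum-mapping-unit
# enforcement, raster-to-vector conversion, event aggregation, attribution.

# Reflection padding index map (edge pixel duplicated): 0 -> 1, -1 -> 2,
# n+1 -> n, n+2 -> n-1.
#' @keywords internal
reflect_index <- function(i, n) {
  i <- ifelse(i < 1, 1 - i, i)
  ifelse(i > n, 2 * n + 1 - i, i)
}

#' Majority (median) filter for a burnt/unburnt raster
#'
#' Each pixel is replaced by the majority value of its `kernel` x `kernel`
#' neighbourhood — for a boolean raster the median and the majority coincide.
#' Removes salt-and-pepper classification noise. Edges are handled by
#' reflection padding (the border pixel is mirrored).
#'
#' @param burn A [burn_raster()].
#' @param kernel Odd window size in pixels (default 3).
#' @return A filtered [burn_raster()].
#' @export
median_filter <- function(burn, kernel = 3) {
  stopifnot(inherits(burn, "burn_raster"))
  kernel <- as.integer(kernel)
  if (kernel < 1 || kernel %% 2 == 0) stop("kernel must be odd and >= 1")
  if (kernel == 1) return(burn)
  h <- (kernel - 1L) %/% 2L
  v <- burn$values
  nr <- nrow(v); nc <- ncol(v)
  ri <- reflect_index(seq(1 - h, nr + h), nr)
  ci <- reflect_index(seq(1 - h, nc + h), nc)
  padded <- v[ri, ci, drop = FALSE] * 1L
  counts <- matrix(0L, nr, nc)
  for (dr in 0:(kernel - 1L)) for (dc in 0:(kernel - 1L))
    counts <- counts + padded[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
  burn_raster(counts * 2L > kernel^2, burn$grid, burn$provenance)
}

# Connected-component labels of a logical matrix (0 = background).
# Components are found as graph components over the pixel-adjacency edges.
#' @keywords internal
label_components <- function(mat, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mat); nc <- ncol(mat)
  on <- which(mat)
  labels <- matrix(0L, nr, nc)
  if (length(on) == 0) return(labels)
  vid <- integer(nr * nc)
  vid[on] <- seq_along(on)
  edge_pairs <- function(dr, dc) {
    rows <- seq_len(nr - abs(dr)) + max(0, -dr)
    cols <- seq_len(nc - abs(dc)) + max(0, -dc)
    a <- mat[rows, cols, drop = FALSE]
    b <- mat[rows + dr, cols + dc, drop = FALSE]
    hit <- which(a & b)
    if (length(hit) == 0) return(NULL)
    r0 <- ((hit - 1L) %% length(rows)) + 1L
    c0 <- ((hit - 1L) %/% length(rows)) + 1L
    i1 <- (rows[r0]) + (cols[c0] - 1L) * nr
    i2 <- (rows[r0] + dr) + (cols[c0] + dc - 1L) * nr
    cbind(vid[i1], vid[i2])
  }
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  edges <- do.call(rbind, lapply(shifts, function(s) edge_pairs(s[1], s[2])))
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  labels[on] <- as.integer(igraph::components(g)$membership)
  labels
}

#' Remove connected components smaller than the minimum mapping unit
#'
#' Components whose area (pixel count x pixel area) is strictly below
#' `mmu_ha` are removed; a component of exactly `mmu_ha` is kept, matching a
#' mapping rule that retains fires of the minimum size and larger. Idempotent.
#'
#' @param burn A [burn_raster()].
#' @param mmu_ha Minimum mapping unit in hectares (default 1).
#' @param connectivity 4 or 8 (default 8: diagonal pixels join a scar).
#' @return A [burn_raster()].
#' @export
remove_small_scars <- function(burn, mmu_ha = 1, connectivity = 8) {
  stopifnot(inherits(burn, "burn_raster"), mmu_ha > 0)
  labels <- label_components(burn$values, connectivity)
  if (max(labels) == 0) return(burn)
  px_ha <- pixel_area_ha(burn$grid)
  counts <- tabulate(labels[labels > 0])
  keep <- which(counts * px_ha >= mmu_ha)
  burn_raster(matrix(labels %in% keep, nrow(labels), ncol(labels)),
              burn$grid, burn$provenance)
}

# ---- polygonization -------------------------------------------------------

# Trace the boundary rings of every labelled component. Directed boundary
# edges keep the component interior on the left, so exterior rings come out
# counter-clockwise (positive shoelace area in world coordinates) and holes
# clockwise. At pinch corners (diagonal pixel contact) the walk takes the
# sharpest right turn, which splits the figure-eight into simple rings.
#' @keywords internal
trace_component_rings <- function(labels, lab, grid) {
  nr <- nrow(labels); nc <- ncol(labels)
  inside <- labels == lab
  pix <- which(inside)
  pr <- ((pix - 1L) %% nr) + 1L
  pc <- ((pix - 1L) %/% nr) + 1L
  neigh <- function(dr, dc) {
    r2 <- pr + dr; c2 <- pc + dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    res <- logical(length(pix))
    res[ok] <- inside[cbind(r2[ok], c2[ok])]
    res
  }
  # corner key for corner (r, c), r in 0..nr, c in 0..nc
  key <- function(r, c) r * (nc + 1L) + c + 1L
  starts <- integer(0); ends <- integer(0); dirs <- integer(0)
  add_edges <- function(s, e, d) {
    starts <<- c(starts, s); ends <<- c(ends, e); dirs <<- c(dirs, d)
  }
  # directions: 0 = +x (E), 1 = +y (N, up = decreasing row), 2 = -x, 3 = -y
  b <- !neigh(1L, 0L)   # bottom side boundary: BL -> BR, dir 0
  add_edges(key(pr[b], pc[b] - 1L), key(pr[b], pc[b]), rep(0L, sum(b)))
  t_ <- !neigh(-1L, 0L) # top side: TR -> TL, dir 2
  add_edges(key(pr[t_] - 1L, pc[t_]), key(pr[t_] - 1L, pc[t_] - 1L),
            rep(2L, sum(t_)))
  l <- !neigh(0L, -1L)  # left side: TL -> BL, dir 3 (downward)
  add_edges(key(pr[l] - 1L, pc[l] - 1L), key(pr[l], pc[l] - 1L),
            rep(3L, sum(l)))
  r <- !neigh(0L, 1L)   # right side: BR -> TR, dir 1 (upward)
  add_edges(key(pr[r], pc[r]), key(pr[r] - 1L, pc[r]), rep(1L, sum(r)))

  n_edges <- length(starts)
  by_start <- split(seq_len(n_edges), starts)
  used <- logical(n_edges)
  rings <- list()
  for (e0 in seq_len(n_edges)) {
    if (used[e0]) next
    ring_keys <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ring_keys <- c(ring_keys, starts[e])
      nxt <- by_start[[as.character(ends[e])]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      if (length(nxt) == 1) { e <- nxt } else {
        # sharpest right turn first: (d-1), then d, then (d+1) (mod 4)
        pref <- (dirs[e] + c(3L, 0L, 1L)) %% 4L
        e <- nxt[order(match(dirs[nxt], pref))][1]
      }
    }
    # corner keys back to world coordinates
    ck <- ring_keys - 1L
    cr <- ck %/% (nc + 1L)
    cc <- ck %% (nc + 1L)
    x <- grid$origin_x + cc * grid$pixel_size_m
    y <- grid$origin_y - cr * grid$pixel_size_m
    m <- cbind(x, y)
    # drop collinear vertices
    n <- nrow(m)
    if (n > 4) {
      prev <- c(n, seq_len(n - 1)); nxt2 <- c(2:n, 1)
      d1 <- m - m[prev, , drop = FALSE]
      d2 <- m[nxt2, , drop = FALSE] - m
      keep <- abs(d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) > 1e-9
      m <- m[keep, , drop = FALSE]
    }
    rings[[length(rings) + 1]] <- m
  }
  rings
}

# Group traced rings into polygons (exterior + contained holes).
#' @keywords internal
rings_to_polygons <- function(rings, pixel_size) {
  areas <- vapply(rings, ring_signed_area, numeric(1))
  ext_idx <- which(areas > 0)
  hole_idx <- which(areas < 0)
  polys <- lapply(ext_idx, function(i) list(rings[[i]]))
  if (length(hole_idx) && length(ext_idx)) {
    for (h in hole_idx) {
      ring <- rings[[h]]
      # representative point just inside the hole: midpoint of the first
      # edge, offset to its right (holes are traced clockwise)
      p1 <- ring[1, ]; p2 <- ring[2, ]
      mid <- (p1 + p2) / 2
      d <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
      pt <- mid + c(d[2], -d[1]) * pixel_size * 0.25
      owner <- which(vapply(ext_idx, function(i)
        points_in_rings(pt[1], pt[2], rings[i]), logical(1)))
      if (length(owner) == 0) owner <- which.max(abs(areas[ext_idx]))
      polys[[owner[1]]] <- c(polys[[owner[1]]], list(ring))
    }
  }
  polys
}

#' Convert a burnt raster into burn-scar polygons
#'
#' One catalog row per connected component. Polygon vertices trace pixel
#' edges; unburnt enclaves inside a scar become interior rings ("donut"
#' holes) whose area is excluded from `area_ha`. A component whose pixels
#' touch only diagonally yields a MultiPolygon (several exterior rings) so
#' every ring stays simple and valid.
#'
#' @param burn A [burn_raster()].
#' @param connectivity 4 or 8 (default 8).
#' @return A [scar_set()] tibble in the grid's CRS.
#' @export
polygonize <- function(burn, connectivity = 8) {
  stopifnot(inherits(burn, "burn_raster"))
  labels <- label_components(burn$values, connectivity)
  n <- max(labels)
  if (n == 0) return(scar_set(list(), crs = burn$grid$crs))
  geoms <- lapply(seq_len(n), function(lab) {
    rings <- trace_component_rings(labels, lab, burn$grid)
    rings_to_polygons(rings, burn$grid$pixel_size_m)
  })
  scar_set(geoms, crs = burn$grid$crs)
}

#' Aggregate nearby scars into fire events
#'
#' Scars whose boundary distance is at most `gap_m` metres share one
#' `event_id` (transitive closure). Geometries are kept separate; the
#' per-event total area is added as `event_area_ha`. With `gap_m = 0` only
#' touching polygons group, i.e. aggregation is effectively off for disjoint
#' scars.
#'
#' @param scars A [scar_set()].
#' @param gap_m Maximum boundary gap in metres (default 0).
#' @return The catalog with `event_id` and `event_area_ha` updated.
#' @export
aggregate_scars <- function(scars, gap_m = 0) {
  stopifnot(gap_m >= 0)
  n <- nrow(scars)
  if (n == 0) return(scars)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    hits <- apply(pairs, 2, function(p)
      geom_boundary_distance(scars$geometry[[p[1]]],
                             scars$geometry[[p[2]]]) <= gap_m)
    if (any(hits)) g <- igraph::add_edges(g, pairs[, hits, drop = FALSE])
  }
  memb <- as.integer(igraph::components(g)$membership)
  scars$event_id <- memb
  ev_area <- tapply(scars$area_ha, memb, sum)
  scars$event_area_ha <- as.numeric(ev_area[as.character(memb)])
  scars
}

# Rasterize one multipolygon onto a grid by pixel-centre membership.
#' @keywords internal
rasterize_geom <- function(geom, grid) {
  nr <- grid$n_rows; nc <- grid$n_cols; s <- grid$pixel_size_m
  cx <- grid$origin_x + (seq_len(nc) - 0.5) * s
  cy <- grid$origin_y - (seq_len(nr) - 0.5) * s
  px <- rep(cx, each = nr)
  py <- rep(cy, times = nc)
  matrix(points_in_geom(px, py, geom), nr, nc)
}

#' Rasterize a scar catalog onto a grid
#'
#' Pixel-centre membership test; pixels whose centre falls inside any scar
#' are marked burnt. Exact for catalogs produced by [polygonize()] on the
#' same grid.
#'
#' @param scars A [scar_set()].
#' @param grid A [geo_grid()].
#' @return Logical matrix.
#' @export
rasterize_scars <- function(scars, grid) {
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (g in scars$geometry) out <- out | rasterize_geom(g, grid)
  out
}

#' Attach area and land-cover attributes to scars
#'
#' Always refreshes `area_ha` from the geometry. If a categorical land-cover
#' raster is given, adds one `lc_<class>` column per class with the burnt
#' hectares of that class inside each scar (zonal pixel counts times pixel
#' area); their sum matches `area_ha` to within one pixel area when the scar
#' edges align with the raster grid.
#'
#' @param scars A [scar_set()].
#' @param landcover Optional [geo_raster()] of integer classes, co-registered
#'   with the scars' CRS.
#' @param class_names Optional named character vector mapping class codes to
#'   column suffixes.
#' @return The catalog with attribute columns added.
#' @export
attribute_scars <- function(scars, landcover = NULL, class_names = NULL) {
  scars$area_ha <- vapply(scars$geometry, function(g) geom_area_m2(g) / 1e4,
                          numeric(1))
  if (is.null(landcover)) return(scars)
  stopifnot(inherits(landcover, "geo_raster"))
  if (!identical(landcover$grid$crs, scar_crs(scars)))
    stop("land-cover CRS (", landcover$grid$crs,
         ") does not match scar CRS (", scar_crs(scars), ")")
  px_ha <- pixel_area_ha(landcover$grid)
  classes <- sort(unique(as.vector(landcover$values)))
  classes <- classes[!is.na(classes)]
  label_of <- function(cl) {
    nm <- if (!is.null(class_names) && as.character(cl) %in% names(class_names))
      class_names[[as.character(cl)]] else as.character(cl)
    paste0("lc_", nm)
  }
  cols <- stats::setNames(vector("list", length(classes)),
                          vapply(classes, label_of, character(1)))
  for (nm in names(cols)) cols[[nm]] <- numeric(nrow(scars))
  for (i in seq_len(nrow(scars))) {
    mask <- rasterize_geom(scars$geometry[[i]], landcover$grid)
    vals <- landcover$values[mask]
    tab <- table(factor(vals, levels = classes))
    for (k in seq_along(classes))
      cols[[label_of(classes[k])]][i] <- as.numeric(tab[k]) * px_ha
  }
  for (nm in names(cols)) scars[[nm]] <- cols[[nm]]
  scars
}
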