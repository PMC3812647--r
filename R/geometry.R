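# Internal planar geometry for pixel-edge (rectilinear) polygons.
#
# Geometries are "multipolygons": a list of polygons, each polygon a list of
# rings, each ring an n x 2 numeric matrix of projected coordinates (metres),
# not closed (the first vertex is not repeated). Ring 1 of a polygon is the
# exterior (counter-clockwise, positive signed area); later rings are holes
# (clockwise). Everything the pipeline produces traces pixel edges, so all
# edges are axis-parallel; the overlay is exact for such input.

#' @keywords internal
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Area of a multipolygon in square metres (holes subtracted).
#' @keywords internal
geom_area_m2 <- function(geom) {
  total <- 0
  for (poly in geom) {
    for (k in seq_along(poly)) {
      a <- abs(ring_signed_area(poly[[k]]))
      total <- total + if (k == 1) a else -a
    }
  }
  total
}

# Even-odd membership of points (px, py) against a set of rings.
# Vectorised over points; loops over edges (rings are short).
#' @keywords internal
points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    xs <- ring[, 1]; ys <- ring[, 2]
    n <- length(xs)
    jj <- c(n, seq_len(n - 1L))
    for (i in seq_len(n)) {
      j <- jj[i]
      crosses <- (ys[i] > py) != (ys[j] > py)
      if (any(crosses)) {
        xint <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
        inside <- xor(inside, crosses & (px < xint))
      }
    }
  }
  inside
}

# Membership in one multipolygon (parity across all its rings: a point inside
# a hole crosses an even number of times and drops out).
#' @keywords internal
points_in_geom <- function(px, py, geom) {
  points_in_rings(px, py, unlist(geom, recursive = FALSE))
}

# Membership in the union of a list of multipolygons (features may overlap).
#' @keywords internal
points_in_union <- function(px, py, geoms) {
  inside <- rep(FALSE, length(px))
  for (g in geoms) inside <- inside | points_in_geom(px, py, g)
  inside
}

#' @keywords internal
geom_is_rectilinear <- function(geoms, tol = 1e-9) {
  for (g in geoms) for (poly in g) for (ring in poly) {
    n <- nrow(ring)
    j <- c(2:n, 1)
    dx <- abs(ring[j, 1] - ring[, 1])
    dy <- abs(ring[j, 2] - ring[, 2])
    if (any(dx > tol & dy > tol)) return(FALSE)
  }
  TRUE
}

#' @keywords internal
geom_coords <- function(geoms) {
  do.call(rbind, lapply(geoms, function(g)
    do.call(rbind, lapply(g, function(p) do.call(rbind, p)))))
}

# Areas (m^2) of intersection and both set differences between the unions of
# two multipolygon lists, by coordinate compression: cut the plane on every
# vertex coordinate of either set and classify each cell by its centre.
# Exact for rectilinear input; otherwise each cell is subsampled on a
# `refine` x `refine` grid (documented approximation).
#' @keywords internal
overlay_cells <- function(det_geoms, ref_geoms, refine = 8L) {
  all_xy <- rbind(geom_coords(det_geoms), geom_coords(ref_geoms))
  xs <- sort(unique(all_xy[, 1]))
  ys <- sort(unique(all_xy[, 2]))
  if (length(xs) < 2 || length(ys) < 2)
    return(c(inter = 0, only_det = 0, only_ref = 0))
  rectil <- geom_is_rectilinear(det_geoms) && geom_is_rectilinear(ref_geoms)
  sub <- if (rectil) 1L else as.integer(refine)

  wx <- diff(xs); wy <- diff(ys)
  inter <- only_det <- only_ref <- 0
  # process one x-slab at a time to bound memory
  for (ix in seq_along(wx)) {
    fr <- (seq_len(sub) - 0.5) / sub
    cx <- xs[ix] + wx[ix] * fr
    cyl <- rep(ys[-length(ys)], each = sub) + rep(wy, each = sub) * fr
    px <- rep(cx, times = length(cyl))
    py <- rep(cyl, each = sub)
    in_d <- points_in_union(px, py, det_geoms)
    in_r <- points_in_union(px, py, ref_geoms)
    cell_a <- (wx[ix] / sub) * rep(rep(wy, each = sub) / sub, each = sub)
    inter <- inter + sum(cell_a[in_d & in_r])
    only_det <- only_det + sum(cell_a[in_d & !in_r])
    only_ref <- only_ref + sum(cell_a[!in_d & in_r])
  }
  c(inter = inter, only_det = only_det, only_ref = only_ref)
}

# Minimum distance between two segments p1-p2 and q1-q2.
#' @keywords internal
segment_distance <- function(p1, p2, q1, q2) {
  pt_seg <- function(p, a, b) {
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
    sqrt(sum((a + t * ab - p)^2))
  }
  orient <- function(a, b, c) sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  # proper intersection => distance 0
  if (orient(p1, p2, q1) * orient(p1, p2, q2) < 0 &&
      orient(q1, q2, p1) * orient(q1, q2, p2) < 0) return(0)
  min(pt_seg(p1, q1, q2), pt_seg(p2, q1, q2), pt_seg(q1, p1, p2), pt_seg(q2, p1, p2))
}

# Minimum boundary distance between two multipolygons.
#' @keywords internal
geom_boundary_distance <- function(g1, g2) {
  rings1 <- unlist(g1, recursive = FALSE)
  rings2 <- unlist(g2, recursive = FALSE)
  best <- Inf
  for (r1 in rings1) {
    n1 <- nrow(r1); j1 <- c(2:n1, 1)
    for (r2 in rings2) {
      n2 <- nrow(r2); j2 <- c(2:n2, 1)
      for (i in seq_len(n1)) {
        # quick reject on bounding distance
        for (k in seq_len(n2)) {
          d <- segment_distance(r1[i, ], r1[j1[i], ], r2[k, ], r2[j2[k], ])
          if (d < best) best <- d
          if (best == 0) return(0)
        }
      }
    }
  }
  best
}

# Axis-aligned rectangle as a single-polygon geometry (CCW ring).
#' @keywords internal
rect_geom <- function(xmin, ymin, xmax, ymax) {
  list(list(matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax),
                   ncol = 2, byrow = TRUE)))
}
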