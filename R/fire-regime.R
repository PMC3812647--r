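# Fire-regime analytics on a catalog of mapped fire events: size
# distribution, dominance of the largest events, altitudinal distribution,
# chi-square land-cover fire-proneness.

#' @keywords internal
as_area_vector <- function(events) {
  if (is.data.frame(events)) {
    col <- intersect(c("area_ha", "event_area_ha"), names(events))
    if (length(col) == 0) stop("events data frame needs an area_ha column")
    events[[col[1]]]
  } else as.numeric(events)
}

#' @keywords internal
interval_labels <- function(edges) {
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  ifelse(is.infinite(hi), paste0(">", format(lo, big.mark = ",")),
         paste0(format(lo, big.mark = ","), "-", format(hi, big.mark = ",")))
}

#' Fire-size distribution
#'
#' Bins fire-event areas into size classes. Intervals are half-open,
#' lower-inclusive `[lo, hi)`, the convention used throughout the package:
#' an event of exactly 1,000 ha falls in the 1,000-5,000 ha class.
#'
#' @param events Numeric vector of event areas in hectares, or a data frame
#'   with an `area_ha` column (e.g. a [scar_set()] collapsed to events).
#' @param edges Ascending bin edges in hectares
#'   (default `c(1, 10, 100, 1000, 5000, Inf)`: classes <10, 10-100,
#'   100-1,000, 1,000-5,000 and >5,000 ha).
#' @return A `fire_size_distribution` tibble with one row per class
#'   (`size_class`, `lower_ha`, `upper_ha`, `n`, `proportion`) and attributes
#'   `total_events` and `total_ha`. Proportions of an empty catalog are `NA`.
#' @export
fire_size_distribution <- function(events,
                                   edges = c(1, 10, 100, 1000, 5000, Inf)) {
  areas <- as_area_vector(events)
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be ascending")
  n_bins <- length(edges) - 1
  counts <- if (length(areas))
    tabulate(findInterval(areas, edges, rightmost.closed = FALSE), n_bins)
  else rep(0L, n_bins)
  total <- length(areas)
  out <- tibble::tibble(size_class = interval_labels(edges),
                        lower_ha = edges[-length(edges)],
                        upper_ha = edges[-1],
                        n = counts,
                        proportion = if (total > 0) counts / total
                                     else rep(NA_real_, n_bins))
  attr(out, "total_events") <- total
  attr(out, "total_ha") <- sum(areas)
  class(out) <- c("fire_size_distribution", class(out))
  out
}

#' Share of the n largest fires
#'
#' Total area of the `n` largest events and their share of the catalog's
#' total burnt area. Monotone non-decreasing in `n`; `n` at or beyond the
#' catalog size gives share 1.
#'
#' @param events As in [fire_size_distribution()].
#' @param n Number of largest events (>= 1).
#' @return One-row tibble: `n`, `largest_ha`, `total_ha`, `share`.
#' @export
largest_n_share <- function(events, n) {
  areas <- as_area_vector(events)
  if (length(areas) == 0) stop("empty event catalog")
  stopifnot(n >= 1)
  top <- sum(sort(areas, decreasing = TRUE)[seq_len(min(n, length(areas)))])
  tibble::tibble(n = as.integer(n), largest_ha = top, total_ha = sum(areas),
                 share = top / sum(areas))
}

#' Altitudinal distribution of burnt area
#'
#' Rasterizes the scar catalog at the DEM grid and tabulates burnt hectares
#' per elevation zone by pixel-wise DEM lookup. Zones are half-open,
#' lower-inclusive: a DEM value of exactly 500 m falls in the 500-1,000 m
#' zone. Rasterization at the DEM resolution bounds the error by one pixel
#' per scar boundary.
#'
#' @param scars A [scar_set()] in the DEM's CRS.
#' @param dem A [geo_raster()] of elevations (m a.s.l.).
#' @param edges Ascending zone edges in metres
#'   (default `c(0, 500, 1000, 1500, Inf)`).
#' @return An `elevation_distribution` tibble: `zone`, `lower_m`, `upper_m`,
#'   `burnt_ha`, `share`.
#' @export
altitudinal_distribution <- function(scars, dem,
                                     edges = c(0, 500, 1000, 1500, Inf)) {
  stopifnot(inherits(dem, "geo_raster"))
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be ascending")
  if (!is.na(scar_crs(scars)) && !identical(scar_crs(scars), dem$grid$crs))
    stop("CRS mismatch between scars (", scar_crs(scars), ") and DEM (",
         dem$grid$crs, ")")
  burnt <- rasterize_scars(scars, dem$grid)
  elev <- dem$values[burnt]
  elev <- elev[!is.na(elev)]
  px_ha <- pixel_area_ha(dem$grid)
  n_zones <- length(edges) - 1
  counts <- if (length(elev))
    tabulate(findInterval(elev, edges, rightmost.closed = FALSE), n_zones)
  else rep(0L, n_zones)
  ha <- counts * px_ha
  out <- tibble::tibble(zone = interval_labels(edges),
                        lower_m = edges[-length(edges)],
                        upper_m = edges[-1],
                        burnt_ha = ha,
                        share = if (sum(ha) > 0) ha / sum(ha)
                                else rep(NA_real_, n_zones))
  class(out) <- c("elevation_distribution", class(out))
  out
}

#' Chi-square land-cover fire-proneness
#'
#' Pearson goodness-of-fit test of whether burnt area distributes across
#' land-cover classes in proportion to each class's share of the landscape.
#' The observed frequency of class c is its burnt area O_c (ha); the expected
#' frequency is the class's landscape share scaled to the total burnt area,
#' `E_c = A_c / sum(A) * total_burnt`. Positive `(O_c - E_c)/E_c` ratios mark
#' fire-prone classes. The statistic is `X^2 = sum (O_c - E_c)^2 / E_c` with
#' `k - 1` degrees of freedom and an upper-tail p-value.
#'
#' @param observed Named numeric vector of burnt hectares per class, or a
#'   data frame with columns `class`, `observed_ha`, `class_area_ha`.
#' @param class_area Named numeric vector of landscape hectares per class
#'   (same classes as `observed`); ignored when `observed` is a data frame.
#' @param total_burnt Total burnt hectares the expectation is scaled to
#'   (default `sum(observed)`, which makes observed and expected totals
#'   match, the standard Pearson setup).
#' @param min_share Drop classes whose landscape share of the analysed
#'   classes is below this proportion (default 0 = keep all).
#' @return A `landcover_proneness` tibble with per-class `observed_ha`,
#'   `expected_ha`, `ratio` ((O-E)/E) and `contribution` ((O-E)^2/E), plus
#'   attributes `statistic`, `df`, `p.value` (see [glance.landcover_proneness()]).
#' @examples
#' landcover_proneness(c(forest = 50, shrub = 50),
#'                     c(forest = 9000, shrub = 1000))
#' @export
landcover_proneness <- function(observed, class_area = NULL,
                                total_burnt = NULL, min_share = 0) {
  if (is.data.frame(observed)) {
    stopifnot(all(c("class", "observed_ha", "class_area_ha") %in%
                    names(observed)))
    classes <- as.character(observed$class)
    obs <- stats::setNames(observed$observed_ha, classes)
    class_area <- stats::setNames(observed$class_area_ha, classes)
    observed <- obs
  }
  if (is.null(names(observed)) || is.null(names(class_area)))
    stop("observed and class_area must be named by land-cover class")
  if (!setequal(names(observed), names(class_area)))
    stop("class sets differ between observed and class_area")
  class_area <- class_area[names(observed)]
  if (any(class_area <= 0)) stop("class areas must be positive")
  if (min_share > 0) {
    keep <- class_area / sum(class_area) >= min_share
    observed <- observed[keep]; class_area <- class_area[keep]
  }
  if (is.null(total_burnt)) total_burnt <- sum(observed)
  if (total_burnt <= 0) stop("total_burnt must be positive")
  expected <- class_area / sum(class_area) * total_burnt
  ratio <- (observed - expected) / expected
  contribution <- (observed - expected)^2 / expected
  x2 <- sum(contribution)
  df <- length(observed) - 1
  out <- tibble::tibble(class = names(observed),
                        observed_ha = as.numeric(observed),
                        expected_ha = as.numeric(expected),
                        ratio = as.numeric(ratio),
                        contribution = as.numeric(contribution))
  attr(out, "statistic") <- x2
  attr(out, "df") <- df
  attr(out, "p.value") <- stats::pchisq(x2, df, lower.tail = FALSE)
  class(out) <- c("landcover_proneness", class(out))
  out
}

#' Tidy land-cover proneness results
#'
#' `tidy()` returns the per-class table; `glance()` the test summary
#' (`statistic`, `df`, `p.value`, totals).
#'
#' @param x A `landcover_proneness` object.
#' @param ... Unused.
#' @method tidy landcover_proneness
#' @export
tidy.landcover_proneness <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "landcover_proneness")
  out
}

#' @rdname tidy.landcover_proneness
#' @method glance landcover_proneness
#' @export
glance.landcover_proneness <- function(x, ...) {
  tibble::tibble(statistic = attr(x, "statistic"),
                 df = attr(x, "df"),
                 p.value = attr(x, "p.value"),
                 total_observed_ha = sum(x$observed_ha),
                 total_expected_ha = sum(x$expected_ha),
                 n_classes = nrow(x))
}
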