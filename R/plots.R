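# ggplot2 displays for the result types.

#' Plot a fire-size distribution
#'
#' Bar chart of event counts (or proportions) per size class.
#'
#' @param object A [fire_size_distribution()] tibble.
#' @param proportion Plot proportions instead of counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fire_size_distribution
#' @export
autoplot.fire_size_distribution <- function(object, proportion = FALSE, ...) {
  df <- tibble::as_tibble(object)
  df$size_class <- factor(df$size_class, levels = df$size_class)
  y <- if (proportion) "proportion" else "n"
  ggplot2::ggplot(df, ggplot2::aes(.data$size_class, .data[[y]])) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "Fire size class (ha)",
                  y = if (proportion) "Proportion of events" else "Events",
                  title = "Fire-size distribution") +
    ggplot2::theme_minimal()
}

#' Plot an altitudinal distribution of burnt area
#'
#' @param object An [altitudinal_distribution()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot elevation_distribution
#' @export
autoplot.elevation_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$zone <- factor(df$zone, levels = df$zone)
  ggplot2::ggplot(df, ggplot2::aes(.data$zone, .data$share)) +
    ggplot2::geom_col(fill = "sienna") +
    ggplot2::labs(x = "Elevation zone (m a.s.l.)", y = "Share of burnt area",
                  title = "Altitudinal distribution of burnt area") +
    ggplot2::theme_minimal()
}

#' Plot land-cover fire-proneness ratios
#'
#' Bars of the (observed - expected)/expected ratio per class; positive bars
#' mark fire-prone classes.
#'
#' @param object A [landcover_proneness()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot landcover_proneness
#' @export
autoplot.landcover_proneness <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$prone <- df$ratio > 0
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$class, .data$ratio),
                                   .data$ratio, fill = .data$prone)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "steelblue")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "(observed - expected) / expected",
                  title = "Land-cover fire-proneness") +
    ggplot2::theme_minimal()
}

# Flatten scar geometries into a plotting frame (one row per vertex).
#' @keywords internal
scar_fortify <- function(scars) {
  rows <- list()
  for (i in seq_len(nrow(scars))) {
    geom <- scars$geometry[[i]]
    for (p in seq_along(geom)) for (r in seq_along(geom[[p]])) {
      ring <- geom[[p]][[r]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        scar_id = scars$scar_id[i], event_id = scars$event_id[i],
        piece = paste(i, p, r, sep = "."), hole = r > 1,
        x = ring[, 1], y = ring[, 2])
    }
  }
  dplyr::bind_rows(rows)
}

#' Plot a burn-scar catalog
#'
#' Scar outlines in projected coordinates, coloured by event. Holes are drawn
#' as outlines too (the fill is not hole-aware; use it as a quick look, not
#' cartography).
#'
#' @param object A [scar_set()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scar_set
#' @export
autoplot.scar_set <- function(object, ...) {
  df <- scar_fortify(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$piece,
                                   colour = factor(.data$event_id))) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)", colour = "Event",
                  title = "Burn-scar polygons") +
    ggplot2::theme_minimal()
}
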