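# Plotting methods. Regional maps are drawn as flat polar projections of the
# spherical parcel coordinates (one disc per hemisphere), the conventional
# quick look at parcel-level cortical maps without surface meshes.

# Internal: attach polar projection coordinates to a geometry tibble.
project_geometry <- function(geometry) {
  theta <- acos(pmin(1, pmax(-1, geometry$x * ifelse(geometry$hemi == "R", 1, -1))))
  phi <- atan2(geometry$z, geometry$y)
  dplyr::mutate(geometry, px = theta * cos(phi), py = theta * sin(phi))
}

#' Plot a regional change map on the parcellation
#'
#' @param object A `change_map` tibble.
#' @param geometry The parcellation tibble the map was computed on.
#' @param value Column to plot (default `"t"`).
#' @param ... Unused.
#' @return A ggplot: polar-projected parcels colored by the statistic, one
#'   facet per hemisphere.
#' @export
autoplot.change_map <- function(object, geometry, value = "t", ...) {
  df <- dplyr::left_join(project_geometry(geometry),
                         tibble::as_tibble(object), by = "region")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py,
                                   colour = .data[[value]])) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~hemi) +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "grey92",
                                    high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = value,
                  title = sprintf("Regional contrast (%s, %s)",
                                  attr(object, "model"), attr(object, "coef")))
}

#' Plot cell-class expression maps
#'
#' @param maps A classes x regions matrix from [cell_class_maps()].
#' @param geometry The parcellation tibble (left hemisphere rows are used).
#' @return A ggplot, one facet per cell class.
#' @export
plot_cell_class_maps <- function(maps, geometry) {
  geom_lh <- project_geometry(geometry[geometry$region %in% colnames(maps), ])
  df <- purrr::map(rownames(maps), function(cl) {
    dplyr::mutate(geom_lh, class = cl,
                  expr = as.numeric(maps[cl, geom_lh$region]))
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py,
                                   colour = .data$expr)) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "grey92",
                                    high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "weighted median z")
}

#' Plot a chromosome median-rank profile
#'
#' @param profile Output of [chromosome_rank_profile()].
#' @param highlight Optional chromosome label to emphasize.
#' @return A ggplot: median centered rank (point) and bootstrap SE (range)
#'   per chromosome.
#' @export
plot_chromosome_profile <- function(profile, highlight = NULL) {
  df <- dplyr::mutate(profile,
                      chromosome = factor(.data$chromosome,
                                          levels = profile$chromosome),
                      cnv = .data$chromosome %in% (highlight %||% character(0)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chromosome,
                                   y = .data$median_rank,
                                   colour = .data$cnv)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$median_rank - .data$se,
                                          ymax = .data$median_rank + .data$se),
                             show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "median centered rank")
}
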