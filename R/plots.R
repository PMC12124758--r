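#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gridded landscape
#'
#' Tile map of the cover classes, optionally overlaying sites. North is up
#' (row 1 at the top).
#'
#' @param object A [grid_landscape()].
#' @param sites Optional site tibble to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_landscape <- function(object, sites = NULL, ...) {
  cc <- cover_codes()
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object$cover)), times = ncol(object$cover)),
    col = rep(seq_len(ncol(object$cover)), each = nrow(object$cover)),
    cover = factor(as.vector(object$cover), levels = unname(cc),
                   labels = names(cc))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$cover)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(FOREST = "#1b7837",
                                          SAVANNA = "#d9f0a3",
                                          WATER = "#4575b4")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (east)", y = "row (south)", fill = "cover")
  if (!is.null(sites)) {
    p <- p + ggplot2::geom_point(
      data = sites, ggplot2::aes(x = .data$col, y = .data$row),
      inherit.aes = FALSE, shape = 21, fill = "white", size = 1.5)
  }
  p
}

#' Plot carrying-capacity estimates against maize yield
#'
#' @param table A [capacity_table()] result.
#' @return A ggplot: capacity per scenario and accessibility panel.
#' @export
plot_capacity <- function(table) {
  long <- tidyr::pivot_longer(
    table, c("forest_only", "savanna_only", "mixed"),
    names_to = "scenario", values_to = "capacity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$maize_yield,
                                     y = .data$capacity,
                                     colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(
      ggplot2::vars(.data$restricted),
      labeller = ggplot2::as_labeller(
        c(`FALSE` = "full landscape", `TRUE` = "within 7 km walk"))) +
    ggplot2::labs(x = "maize yield (kg/ha/yr)",
                  y = "carrying capacity (persons)")
}

#' Plot the mean yearly trajectory of an ensemble
#'
#' @param object A [run_ensemble()] result.
#' @param what `"population"` or `"settlements_total"`.
#' @param ... Unused.
#' @return A ggplot of per-run series with the cross-run mean overlaid.
#' @export
autoplot.ensemble_result <- function(object, what = "population", ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$year, y = .data[[what]],
                               group = .data$run)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_line(data = object$mean_series, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$year, y = .data[[what]]),
                       linewidth = 1) +
    ggplot2::labs(x = "year", y = what)
}

#' Plot the components of a spatial-configuration score
#'
#' @param object A [distance_score()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of the seven components (km).
#' @export
autoplot.spatial_score <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$component, y = .data$km)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "absolute difference (km)")
}
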