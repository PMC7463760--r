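#' Plot a per-cell surface
#'
#' Tile map of any per-cell numeric column, on the package's row-major
#' north-west-origin grid (row 0 at the top).
#'
#' @param data tibble with `row`, `col` and the value column (join metric or
#'   delta tibbles with the geometry first if needed).
#' @param fill name of the column to map to fill.
#' @return a ggplot.
#' @export
plot_surface <- function(data, fill) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$col, y = -.data$row,
                                     fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey40") +
    ggplot2::labs(x = NULL, y = NULL, fill = fill) +
    ggplot2::theme_minimal()
}

canape_palette <- c(
  neo = "#d7301f", paleo = "#0570b0", mixed = "#c994c7", super = "#6a51a3",
  not_significant = "#f7f4f9", no_data = "grey40"
)

#' Plot a CANAPE endemism-center map
#'
#' Conventional coloring: neo red, paleo blue, mixed light purple, super
#' dark purple; no-data cells dark grey.
#'
#' @param canape tibble from [canape_classify()].
#' @param geometry [grid_geometry()] tibble (or covariates) for the cells.
#' @return a ggplot.
#' @export
plot_canape <- function(canape, geometry) {
  d <- dplyr::inner_join(canape, geometry[, c("cell", "row", "col")], by = "cell")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = -.data$row,
                                  fill = .data$category)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = canape_palette, drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "endemism center") +
    ggplot2::theme_minimal()
}

#' Plot a bioregionalization
#'
#' @param reg a `regionalization` tibble.
#' @param geometry [grid_geometry()] tibble for the cells.
#' @return a ggplot.
#' @export
plot_regionalization <- function(reg, geometry) {
  d <- dplyr::inner_join(tibble::as_tibble(reg), geometry[, c("cell", "row", "col")],
                         by = "cell")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = -.data$row,
                                  fill = factor(.data$cluster))) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "sector") +
    ggplot2::theme_minimal()
}

#' Plot a Moran correlogram
#'
#' Residual autocorrelation per distance class, with the null expectation.
#'
#' @param correlogram tibble from [moran_correlogram()].
#' @return a ggplot.
#' @export
plot_correlogram <- function(correlogram) {
  ggplot2::ggplot(correlogram, ggplot2::aes(x = .data$midpoint, y = .data$moran_i)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$expected), linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance class midpoint", y = "Moran's I") +
    ggplot2::theme_minimal()
}
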