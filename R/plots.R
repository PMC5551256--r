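#' Plot a categorical land-cover grid
#'
#' @param object A [land_cover_grid()].
#' @param ... Unused.
#' @return A ggplot: cell tiles filled by class name.
#' @export
autoplot.land_cover_grid <- function(object, ...) {
  df <- grid_to_df(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$date_label, fill = "class") +
    ggplot2::theme_minimal()
}

grid_to_df <- function(grid) {
  v <- grid$values
  nd <- legend_nodata(grid$legend)
  df <- tibble::tibble(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    code = as.vector(v)
  )
  df <- df[df$code != nd, ]
  df$class <- legend_names(grid$legend)[match(df$code,
                                              legend_codes(grid$legend))]
  df
}

#' Plot a transition matrix as a heatmap
#'
#' Off-diagonal tiles show where area moved between classes; the diagonal
#' (persistence) usually dominates and is best read from the printed matrix.
#'
#' @param object A [transition_matrix()].
#' @param ... Unused.
#' @return A ggplot tile map of converted areas (km2).
#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$area_km2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::labs(x = "class at period end", y = "class at period start",
                  fill = "km2") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-class ESV
#'
#' @param object An `esv_result` from [esv_totals()].
#' @param ... Unused.
#' @return A ggplot bar chart of ESV by class (1e9 Yuan).
#' @export
autoplot.esv_result <- function(object, ...) {
  df <- object$by_class
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$class,
                                                      -.data$esv_yuan),
                                   y = .data$esv_yuan / 1e9)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "ESV (1e9 Yuan)", title = object$year_label) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-zone sensitivity indices
#'
#' @param si Tibble from [si_by_zone()].
#' @return A ggplot bar chart of SI by zone; undefined zones are dropped.
#' @export
plot_si_by_zone <- function(si) {
  df <- si[!is.na(si$si), ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$zone), y = .data$si)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "zone", y = "sensitivity index") +
    ggplot2::theme_minimal()
}
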