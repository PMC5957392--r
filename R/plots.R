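#' Plot a habitat raster
#'
#' @param object A [landscape_raster()].
#' @param ... Unused.
#' @return A ggplot tile map with one fill level per habitat class.
#' @export
autoplot.landscape_raster <- function(object, ...) {
  cells <- tidy(object)
  ggplot2::ggplot(cells, ggplot2::aes(
    x = .data$col, y = .data$row, fill = .data$class
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Habitat")
}

#' Plot an invasion trajectory
#'
#' Adult population total and occupied-cell count over time.
#'
#' @param object An `invasion_run` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot with one free-scaled panel per series.
#' @export
autoplot.invasion_run <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trajectory[, c("year", "population", "occupied")],
    c("population", "occupied"),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "Year", y = NULL)
}

#' Plot relative importances of landscape metrics
#'
#' Bar chart of coefficient magnitudes scaled to the strongest predictor, in
#' metric-registry order, signed by fill color (negative mean coefficients
#' in red).
#'
#' @param importances Output of [relative_importance()].
#' @return A ggplot.
#' @export
plot_relative_importance <- function(importances) {
  reg <- metric_registry()
  df <- dplyr::left_join(importances, reg[, c("name", "position")],
    by = c(metric = "name")
  )
  df$position <- df$position %||% seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$relative_importance,
    fill = .data$sign == "-"
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::geom_vline(xintercept = 11.5, linetype = "dashed") +
    ggplot2::labs(
      x = "Landscape metric (registry order; left of dashed = composition)",
      y = "Relative importance |beta| / max |beta|"
    )
}
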