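#' @export
autoplot.reference_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$doy, y = .data$ndvi)) +
    ggplot2::geom_line(color = "forestgreen") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Day of year", y = "NDVI",
                  title = sprintf("Standard %s maize curve", object$season)) +
    ggplot2::theme_minimal()
}

.raster_df <- function(m, value_name) {
  tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
         col = rep(seq_len(ncol(m)), each = nrow(m)),
         value = as.vector(m)) |>
    setNames(c("row", "col", value_name))
}

#' @export
autoplot.maize_map <- function(object, ...) {
  df <- .raster_df(object$values, "maize")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = factor(.data$maize))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey90", `1` = "darkgreen"),
                               na.value = "white", name = NULL,
                               labels = c(`0` = "other", `1` = "maize")) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Maize map, %d", object$year),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @export
autoplot.dissimilarity_map <- function(object, ...) {
  df <- .raster_df(object$distance, "distance")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "TWDTW dissimilarity", x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @export
autoplot.frequency_map <- function(object, ...) {
  df <- .raster_df(object$count, "years")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$years)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "maize years") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Planting frequency over %d years",
                                  object$n_years), x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Histogram of patch sizes on a log axis
#'
#' @param sizes integer vector of patch sizes (see [patch_sizes()]).
#' @return A ggplot.
#' @export
plot_patch_sizes <- function(sizes) {
  ggplot2::ggplot(tibble(size = sizes), ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(bins = 30, fill = "darkgreen", color = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Patch size (pixels)", y = "Patches") +
    ggplot2::theme_minimal()
}
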