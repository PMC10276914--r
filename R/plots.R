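# ggplot2 views of the main result types.

#' Plot one channel of an image stack
#'
#' @param stack An [image_stack()].
#' @param channel Channel role or index.
#' @param z Z-slice, or `"max"` for the maximum projection.
#' @return A ggplot raster plot (origin top-left, like the image).
#' @export
plot_field <- function(stack, channel = 1L, z = "max") {
  plane <- if (identical(z, "max")) max_project(stack, channel) else
    get_plane(stack, channel, z)
  df <- tidyr::expand_grid(row = seq_len(nrow(plane)) - 1L,
                           col = seq_len(ncol(plane)) - 1L)
  df$intensity <- as.vector(t(plane))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)", fill = "a.u.")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a current trace with detected events
#'
#' @param object An `epsc_trace`.
#' @param events Optional `epsc_events` tibble; detected onsets are marked.
#' @param ... Unused.
#' @return A ggplot line plot.
#' @method autoplot epsc_trace
#' @export
autoplot.epsc_trace <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$current_pa)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "current (pA)")
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_vline(data = events,
                                 ggplot2::aes(xintercept = .data$time_s),
                                 colour = "red", alpha = 0.5,
                                 linetype = "dashed")
  }
  p
}

#' Plot deposit size-class counts of an inclusion result
#'
#' @param object An `inclusion_result` from [quantify_inclusions()].
#' @param ... Unused.
#' @return A ggplot bar chart of particle counts per size class.
#' @method autoplot inclusion_result
#' @export
autoplot.inclusion_result <- function(object, ...) {
  df <- dplyr::count(object$particles, .data$size_class, .drop = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(.data$size_class, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "size class", y = "particles")
}
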