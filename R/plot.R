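#' Topographic scatter plot of a group-comparison map
#'
#' Mirrors the usual presentation of channel-wise group differences:
#' electrode positions drawn on a schematic head, point color encoding the
#' direction of the difference (red = control higher, blue = control
#' lower), point size the significance tier of the FDR-adjusted p-value.
#' Requires ggplot2.
#'
#' @param stats_map a \code{group_stats} data.frame from
#'   \code{\link{topographic_group_map}}.
#' @param positions (n_channels x 2) electrode coordinates with rownames;
#'   default standard 10-20.
#' @param statistic \code{"temporal"} or \code{"spatial"}.
#' @return a ggplot object (facetted by class).
#' @export
plot_group_topography <- function(stats_map,
                                  positions = standard_1020_positions(),
                                  statistic = "temporal") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- stats_map[stats_map$statistic == statistic, ]
  d$x <- positions[d$channel, 1L]
  d$y <- positions[d$channel, 2L]
  d$size <- c(ns = 1.5, `p<0.05` = 3, `p<0.01` = 5)[d$tier]
  circ <- data.frame(x = 1.15 * cos(seq(0, 2 * pi, length.out = 120)),
                     y = 1.15 * sin(seq(0, 2 * pi, length.out = 120)))
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_path(data = circ, inherit.aes = FALSE,
                       ggplot2::aes(x = x, y = y),
                       color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = direction,
                                     size = size)) +
    ggplot2::scale_color_manual(values = c("control>patient" = "red3",
                                           "control<patient" = "blue3")) +
    ggplot2::scale_size_identity() +
    ggplot2::facet_wrap(~class) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste(statistic, "variability: group differences"),
                  color = NULL)
}
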