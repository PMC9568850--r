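#' Plot channel width against radial position
#'
#' Box-and-whisker display of the retained channel widths at each sampled
#' radius (boxes: interquartile range; whiskers: 1.5 x IQR clamped to the
#' data; white diamonds: means), the standard way these radial series are
#' summarised.
#'
#' @param x A `channel_measurement` or a channel width table with a
#'   `retained` column.
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the per-radius width list.
#' @export
plot_radial_series <- function(x, ...) {
  tab <- if (inherits(x, "channel_measurement")) x$widths else x
  if (!is.null(tab$retained)) tab <- tab[tab$retained, , drop = FALSE]
  if (!nrow(tab)) stop("no retained widths to plot", call. = FALSE)
  groups <- split(tab$width_um, tab$radius_um)
  graphics::boxplot(groups, xlab = "radius (um)",
                    ylab = "channel width (um)", range = 1.5, ...)
  graphics::points(seq_along(groups), vapply(groups, mean, 0),
                   pch = 23, bg = "white", cex = 1.2)
  invisible(groups)
}

#' @export
plot.channel_measurement <- function(x, ...) {
  plot_radial_series(x, main = sprintf("%s (%s)", x$biofilm_id,
                                       x$condition), ...)
}
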