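#' Plot methods for neuromove result objects
#'
#' `autoplot()` methods give quick diagnostic figures: the cursor path with
#' the circular tunnel, the block-averaged hemodynamic response per
#' channel, and the time-frequency ERSP map.
#'
#' @param object A `cursor_trace`, `hemo_epoch` or `ersp_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name neuromove-plots
NULL

#' @rdname neuromove-plots
#' @method autoplot cursor_trace
#' @export
autoplot.cursor_trace <- function(object, ...) {
  geom <- attr(object, "geometry")
  ang <- seq(0, 2 * pi, length.out = 361)
  ring <- function(r) {
    tibble(x = geom$center[1] + r * cos(ang),
           y = geom$center[2] + r * sin(ang))
  }
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = ring(geom$radius - geom$tunnel_width / 2),
                       linetype = 2, colour = "grey50") +
    ggplot2::geom_path(data = ring(geom$radius + geom$tunnel_width / 2),
                       linetype = 2, colour = "grey50") +
    ggplot2::geom_path(alpha = 0.7, colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Cursor path and steering tunnel")
}

#' @rdname neuromove-plots
#' @method autoplot hemo_epoch
#' @export
autoplot.hemo_epoch <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("hbo", "hbr"), names_to = "chromophore",
                        values_to = "conc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rel_time, y = .data$conc,
                                     colour = .data$chromophore)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_colour_manual(
      values = c(hbo = "firebrick", hbr = "navy"),
      labels = c(hbo = "HbO2", hbr = "HbR")
    ) +
    ggplot2::labs(x = "time from task onset (s)",
                  y = expression(Delta * "Hb (uM)"),
                  title = "Block-averaged hemodynamic response")
}

#' @rdname neuromove-plots
#' @method autoplot ersp_map
#' @export
autoplot.ersp_map <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$rel_time, y = .data$frequency,
                               fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "time from task onset (s)", y = "frequency (Hz)",
                  fill = "dB",
                  title = "Event-related spectral perturbation")
}
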