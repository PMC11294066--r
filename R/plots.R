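#' Plot a COD trace
#'
#' Per-axis COD against time, with a statistical-noise band and detected
#' motion times, the standard diagnostic view of the motion detector.
#'
#' @param object a `cod_trace`.
#' @param motion_times_s optional detected motion times to mark.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cod_trace
#' @export
autoplot.cod_trace <- function(object, motion_times_s = NULL, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "bin_start_s", dplyr::starts_with("cod_"),
                  dplyr::starts_with("sigma_")),
    cols = -"bin_start_s",
    names_to = c(".value", "axis"),
    names_pattern = "(cod|sigma)_([xyz])_mm")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_start_s, y = .data$cod)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cod - 2 * .data$sigma,
                                      ymax = .data$cod + 2 * .data$sigma),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "COD (mm)")
  if (length(motion_times_s))
    p <- p + ggplot2::geom_vline(xintercept = motion_times_s,
                                 colour = "firebrick", linetype = 2)
  p
}

#' Plot a regional report
#'
#' Per-region percent change as a horizontal bar chart.
#'
#' @param object a `region_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot region_report
#' @export
autoplot.region_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$percent_change,
                               y = stats::reorder(.data$region,
                                                  .data$percent_change))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "SUV mean change (%)", y = NULL)
}

#' Plot an axial slice of a volume
#'
#' @param vol an [image_volume()].
#' @param slice 1-based axial slice index (default: middle).
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, slice = NULL) {
  d <- dim(vol)
  if (is.null(slice)) slice <- (d[3] + 1L) %/% 2L
  df <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$value <- as.numeric(unclass(vol)[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice %d", slice), x = NULL, y = NULL)
}
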