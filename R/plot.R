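# Scan figures: per-site delta points, the sliding-window mean and the
# simulated confidence threshold, with candidate regions shaded.

#' Plot a Delta(SNP-index) scan
#'
#' One panel per chromosome: per-site delta as points, the sliding-window
#' mean as a line, the depth-matched upper confidence threshold as a second
#' line, and called candidate regions shaded.
#'
#' @param scan A `delta_scan` from [call_candidate_regions()].
#' @param records Optional per-site SNP-index records (the passing set) to
#'   draw as points.
#' @return A ggplot object.
#' @export
plot_delta_scan <- function(scan, records = NULL) {
  w <- scan$windows
  w$mid <- (w$start + w$end) / 2
  p <- ggplot2::ggplot()
  if (nrow(scan$regions)) {
    p <- p + ggplot2::geom_rect(
      data = scan$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      fill = "gold", alpha = 0.3
    )
  }
  if (!is.null(records)) {
    p <- p + ggplot2::geom_point(
      data = records,
      ggplot2::aes(x = .data$pos / 1e6, y = .data$delta),
      colour = "steelblue", alpha = 0.25, size = 0.4
    )
  }
  p +
    ggplot2::geom_line(data = w,
                       ggplot2::aes(x = .data$mid / 1e6, y = .data$mean_delta),
                       colour = "red") +
    ggplot2::geom_line(data = w,
                       ggplot2::aes(x = .data$mid / 1e6, y = .data$threshold),
                       colour = "darkgreen", linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(Delta * "(SNP-index)")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_delta_scan
#' @param object A `delta_scan`.
#' @param ... Passed to [plot_delta_scan()].
#' @importFrom ggplot2 autoplot
#' @method autoplot delta_scan
#' @export
autoplot.delta_scan <- function(object, ...) plot_delta_scan(object, ...)

#' Plot a simulated null threshold curve
#'
#' Upper and lower null Delta(SNP-index) quantiles against read depth.
#'
#' @param curve A `threshold_curve`.
#' @return A ggplot object.
#' @export
plot_threshold_curve <- function(curve) {
  long <- tidyr::pivot_longer(tibble::as_tibble(curve), c("lower", "upper"),
                              names_to = "bound", values_to = "delta")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$depth, y = .data$delta,
                                     colour = .data$bound)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "read depth (fold)", y = expression(Delta * "(SNP-index)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_delta_scan
#' @method autoplot threshold_curve
#' @export
autoplot.threshold_curve <- function(object, ...) plot_threshold_curve(object)
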