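#' Plot a calendar-time series
#'
#' Time runs forward to the right: the cal BP axis is reversed.
#'
#' @param object A [grid_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cal_bp, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "cal BP", y = attr(object, "label") %||% "value") +
    ggplot2::theme_minimal()
}

#' Plot a power spectrum on the period axis
#'
#' @param object A `spectrum_result` from [power_spectrum()].
#' @param max_period Longest period shown (a).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum_result <- function(object, max_period = 2000, ...) {
  df <- object[object$period <= max_period, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "period (a)", y = "power") +
    ggplot2::theme_minimal()
}

#' Debug scatter of a region partition
#'
#' @param object A `region_partition` from [cluster_regions()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_partition <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cell_lon, y = .data$cell_lat,
                                       color = factor(.data$region),
                                       size = abs(.data$score))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lon", y = "lat", color = "region", size = "|score|") +
    ggplot2::theme_minimal()
}

#' Original versus aligned proxy timings
#'
#' Shows each record's cumulative displacement against its original
#' chronology; the hard cap appears as horizontal guides.
#'
#' @param object A `proxy_alignment` from [align_records()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.proxy_alignment <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$cal_bp_orig, y = .data$displacement,
                               color = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-object$cap, object$cap), linetype = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "original cal BP", y = "displacement (a)") +
    ggplot2::theme_minimal()
}

#' Two preprocessed series with the reference's boom/bust phases shaded
#'
#' @param a Reference series (shaded phases), a [grid_series()].
#' @param b Comparison series.
#' @param peak_eps Peak threshold, as in [phase_overlap()].
#' @return A ggplot.
#' @export
plot_phase_comparison <- function(a, b, peak_eps = NULL) {
  eps <- peak_eps %||% (0.05 * sd(a$value, na.rm = TRUE))
  runs <- peak_runs(a$value, eps)
  shade <- tibble::tibble(
    xmin = a$cal_bp[runs$start], xmax = a$cal_bp[runs$end],
    sign = factor(runs$sign, c(-1, 1), c("bust", "boom"))
  )
  df <- dplyr::bind_rows(
    tibble::tibble(cal_bp = a$cal_bp, value = a$value, series = "reference"),
    tibble::tibble(cal_bp = b$cal_bp, value = b$value, series = "comparison")
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf, fill = .data$sign),
                       alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_line(ggplot2::aes(x = .data$cal_bp, y = .data$value,
                                    color = .data$series), na.rm = TRUE) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "cal BP", y = "normalized value") +
    ggplot2::theme_minimal()
}
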