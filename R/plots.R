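# ggplot2 views of the emitted statistics. Each returns a ggplot object the
# caller can restyle; nothing is printed or written here.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

elapsed_hours <- function(t_s) t_s / 3600

#' Plot a windowed or cumulative metric over elapsed run time
#'
#' @param windows a [window_stats()] / [cumulative_stats()] tibble.
#' @param metric column to plot (default `"yield_bases"`).
#' @return A ggplot.
#' @export
plot_windowed <- function(windows, metric = "yield_bases") {
  stopifnot(metric %in% names(windows))
  ggplot2::ggplot(windows,
                  ggplot2::aes(x = elapsed_hours(.data$t_start),
                               y = .data[[metric]])) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = "elapsed time (h)", y = metric)
}

#' Spatial map of a metric on the flowcell channel grid
#'
#' Quiet or failing regions of the flowcell (bubbles, contamination) show up
#' as structure on this grid. The overflow bucket (channel `NA`), if any, is
#' not drawable and is dropped.
#'
#' @param channels a [channel_stats()] tibble.
#' @param metric column to map (default `"n_reads"`).
#' @return A ggplot.
#' @export
plot_channel_grid <- function(channels, metric = "n_reads") {
  stopifnot(metric %in% names(channels))
  drawable <- channels[!is.na(channels$grid_row), ]
  ggplot2::ggplot(drawable,
                  ggplot2::aes(x = .data$grid_col, y = .data$grid_row,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = metric)
}

#' Plot a read-length distribution
#'
#' @param length_dist a [length_histogram()] tibble (with `percent_bases` for
#'   `mode = "percent_bases"`, see [percent_base_distribution()]).
#' @param mode `"reads"`, `"bases"` or `"percent_bases"`.
#' @return A ggplot.
#' @export
plot_length_dist <- function(length_dist, mode = c("reads", "bases", "percent_bases")) {
  mode <- match.arg(mode)
  ycol <- switch(mode, reads = "read_count", bases = "base_count",
                 percent_bases = "percent_bases")
  stopifnot(ycol %in% names(length_dist))
  ggplot2::ggplot(length_dist,
                  ggplot2::aes(x = .data$bin_start / 1000, y = .data[[ycol]])) +
    ggplot2::geom_col(width = length_dist$bin_width[1] / 1000) +
    ggplot2::labs(x = "read length (kb)", y = switch(mode,
      reads = "reads", bases = "bases", percent_bases = "% of bases"))
}

#' Heatmap of read counts over quality and elapsed time
#'
#' @param qt a [quality_time_histogram()] tibble.
#' @return A ggplot.
#' @export
plot_quality_time <- function(qt) {
  ggplot2::ggplot(qt, ggplot2::aes(x = elapsed_hours(.data$t_start),
                                   y = .data$q_start,
                                   fill = .data$n_reads)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "elapsed time (h)", y = "mean q-score", fill = "reads")
}

#' Overlay a compared metric across runs
#'
#' @param comparison a long table from [compare_runs()] / [compare_yield()]
#'   (`run_id`, `elapsed_s`, `value`) or [compare_length_dist()] (`run_id`,
#'   `bin_start`, `value`).
#' @return A ggplot with one line per run.
#' @export
plot_run_comparison <- function(comparison) {
  xcol <- if ("elapsed_s" %in% names(comparison)) "elapsed_s" else "bin_start"
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data[[xcol]], y = .data$value,
                               colour = .data$run_id)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = xcol, y = "value", colour = "run")
}

#' @describeIn run_accumulator Plot a run accumulator: windowed (or
#'   cumulative) series of one metric.
#' @param object a `run_accumulator`.
#' @param metric column of [window_stats()] to plot.
#' @param cumulative plot running totals instead of per-window values.
#' @param ... unused.
#' @export
autoplot.run_accumulator <- function(object, metric = "yield_bases",
                                     cumulative = FALSE, ...) {
  src <- if (cumulative) cumulative_stats(object) else window_stats(object)
  plot_windowed(src, metric)
}
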