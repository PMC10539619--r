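# ggplot2 views of the result objects.

#' Plot a recording model
#'
#' One panel per continuous trace with comment times and recognized spike
#' times overlaid as rugs, the way a session is eyeballed for plausibility.
#' Long traces are thinned to at most `max_points` samples per trace before
#' plotting.
#'
#' @param object a `dps_recording`.
#' @param max_points per-trace sample budget for drawing.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @method autoplot dps_recording
autoplot.dps_recording <- function(object, max_points = 20000, ...) {
  trace_df <- dplyr::bind_rows(lapply(object$traces, function(tr) {
    n <- length(tr$samples)
    tt <- if (is.null(tr$sampling_interval_s)) tr$times_s
      else tr$start_time_s + (seq_len(n) - 1) * tr$sampling_interval_s
    keep <- if (n > max_points) unique(round(seq(1L, n, length.out = max_points))) else seq_len(n)
    tibble::tibble(trace = tr$name, time = tt[keep], amplitude = tr$samples[keep])
  }))
  p <- ggplot2::ggplot(trace_df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.25, colour = "grey25") +
    ggplot2::facet_wrap(~trace, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "amplitude", title = "recording overview") +
    ggplot2::theme_minimal()
  events <- dplyr::bind_rows(object$events)
  if (!is.null(events) && nrow(events) > 0)
    p <- p + ggplot2::geom_rug(data = dplyr::select(events, time = "time"),
                               ggplot2::aes(x = .data$time), inherit.aes = FALSE,
                               colour = "firebrick", sides = "t")
  spikes <- dplyr::bind_rows(object$spikes)
  if (!is.null(spikes) && nrow(spikes) > 0)
    p <- p + ggplot2::geom_rug(data = dplyr::select(spikes, time = "recognized_time"),
                               ggplot2::aes(x = .data$time), inherit.aes = FALSE,
                               colour = "steelblue", sides = "b")
  p
}

#' Plot a verification report
#'
#' Bar chart of the report tallies, with the maximum absolute difference in
#' the subtitle.
#'
#' @param object a `dps_comparison`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @method autoplot dps_comparison
autoplot.dps_comparison <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$statistic != "max_abs_difference", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      title = sprintf("stream \"%s\" vs CSV (%s mode)", object$stream, object$mode),
      subtitle = sprintf("max |difference| = %g", object$max_abs_difference),
      x = NULL, y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
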