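#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for analysis results
#'
#' `tidy()` returns the per-event (or per-window) table underlying a result;
#' `glance()` returns its one-row summary.
#'
#' @param x a `ms_precision`, `ms_lag` or `ms_woody` object.
#' @param ... unused.
#' @return a tibble.
#' @name multisync-tidiers
NULL

#' @rdname multisync-tidiers
#' @export
tidy.ms_precision <- function(x, ...) x$per_event

#' @rdname multisync-tidiers
#' @export
glance.ms_precision <- function(x, ...) {
  tibble::tibble(
    mean_latency_s = x$mean, sd_latency_s = x$sd,
    min_latency_s = x$min, max_latency_s = x$max, n_events = x$n
  )
}

#' @rdname multisync-tidiers
#' @export
tidy.ms_lag <- function(x, ...) x$per_event

#' @rdname multisync-tidiers
#' @export
glance.ms_lag <- function(x, ...) {
  tibble::tibble(
    session_mean_s = x$session_mean,
    session_abs_mean_s = x$session_abs_mean,
    n_events = nrow(x$per_event)
  )
}

#' @rdname multisync-tidiers
#' @export
tidy.ms_woody <- function(x, ...) {
  tibble::tibble(
    shift_s = x$shift, magnitude = x$magnitude, correlation = x$correlation
  )
}

#' @rdname multisync-tidiers
#' @export
glance.ms_woody <- function(x, ...) tidy.ms_woody(x)

#' Plot per-event marking latencies
#'
#' @param object a `ms_precision`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ms_precision <- function(object, ...) {
  df <- object$per_event
  df$event <- seq_len(nrow(df))
  p <- ggplot2::ggplot(df,
    ggplot2::aes(x = .data$event, y = 1e3 * .data$latency_s))
  if ("session" %in% names(df)) {
    p <- p + ggplot2::aes(colour = factor(.data$session))
  }
  p +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1e3 * object$mean, linetype = "dashed") +
    ggplot2::labs(x = "event", y = "marking latency (ms)", colour = "session")
}
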