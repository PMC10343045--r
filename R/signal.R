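#' Uniformly sampled signal as a tibble
#'
#' A `ms_signal` is a tibble with columns `time` (seconds on the recording
#' device's clock) and `value`, carrying the sampling rate, start time,
#' channel label and units as attributes. Sample `i` (0-based) sits at
#' `start + i / rate`; all package functions use this convention.
#'
#' @param value numeric vector of samples (finite, length >= 1).
#' @param rate sampling rate in Hz (> 0).
#' @param start time of the first sample in seconds on the device clock.
#' @param label channel label.
#' @param units unit string (e.g. "uV", "a.u.").
#' @return a tibble of class `ms_signal` with columns `time`, `value`.
#' @examples
#' s <- signal_ts(sin(2 * pi * 2 * (0:249) / 250), rate = 250, label = "demo")
#' sig_rate(s)
#' @export
signal_ts <- function(value, rate, start = 0, label = "signal", units = "a.u.") {
  if (!is.numeric(value) || length(value) < 1L) {
    ms_abort("`value` must be a non-empty numeric vector", "argument")
  }
  if (!all(is.finite(value))) {
    ms_abort("`value` must be finite", "argument")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    ms_abort("`rate` must be a single positive number (Hz)", "argument")
  }
  if (!is.numeric(start) || length(start) != 1L || !is.finite(start)) {
    ms_abort("`start` must be a single finite number (seconds)", "argument")
  }
  out <- tibble::tibble(
    time = start + (seq_along(value) - 1) / rate,
    value = as.double(value)
  )
  attr(out, "rate") <- as.double(rate)
  attr(out, "start") <- as.double(start)
  attr(out, "label") <- as.character(label)
  attr(out, "units") <- as.character(units)
  class(out) <- c("ms_signal", class(tibble::tibble()))
  out
}

#' Coerce a data frame to a `ms_signal`
#'
#' Accepts a data frame with columns `time`/`value` or `time_s`/`value`. The
#' sampling rate is taken from `rate` if given, otherwise inferred from the
#' time stamps, which must be uniform to within 0.1%.
#'
#' @param x data frame.
#' @param rate sampling rate in Hz; inferred from `time` when `NULL`.
#' @inheritParams signal_ts
#' @return a `ms_signal` tibble.
#' @export
as_signal <- function(x, rate = NULL, label = "signal", units = "a.u.") {
  if (inherits(x, "ms_signal")) return(x)
  if (!is.data.frame(x)) ms_abort("`x` must be a data frame", "argument")
  tcol <- intersect(c("time", "time_s"), names(x))[1]
  if (is.na(tcol) || !"value" %in% names(x)) {
    ms_abort("`x` needs columns `time` (or `time_s`) and `value`", "argument")
  }
  tt <- as.double(x[[tcol]])
  if (length(tt) < 2L && is.null(rate)) {
    ms_abort("cannot infer `rate` from fewer than 2 samples", "argument")
  }
  if (is.null(rate)) rate <- 1 / stats::median(diff(tt))
  dev <- abs(diff(tt) - 1 / rate) * rate
  if (length(dev) && max(dev) > 1e-3) {
    ms_abort(
      sprintf("time stamps deviate from a uniform %g Hz grid by more than 0.1%%", rate),
      "argument"
    )
  }
  signal_ts(x[["value"]], rate = rate, start = tt[1], label = label, units = units)
}

#' @rdname signal_ts
#' @param x a `ms_signal`.
#' @export
sig_rate <- function(x) attr(x, "rate")

#' @rdname signal_ts
#' @export
sig_start <- function(x) attr(x, "start")

#' @rdname signal_ts
#' @export
sig_label <- function(x) attr(x, "label")

#' @rdname signal_ts
#' @export
sig_units <- function(x) attr(x, "units")

#' @rdname signal_ts
#' @export
sig_duration <- function(x) (nrow(x) - 1) / sig_rate(x)

# replace the sample vector, keeping grid metadata
set_values <- function(x, value) {
  signal_ts(value,
    rate = sig_rate(x), start = sig_start(x),
    label = sig_label(x), units = sig_units(x)
  )
}

#' @export
print.ms_signal <- function(x, ...) {
  cat(sprintf(
    "<ms_signal> %s [%s]: %d samples @ %g Hz, start %.6f s\n",
    sig_label(x), sig_units(x), nrow(x), sig_rate(x), sig_start(x)
  ))
  NextMethod()
}

#' Plot a signal trace
#'
#' @param object a `ms_signal`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ms_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = sig_units(object),
      title = sig_label(object)
    )
}

ms_abort <- function(message, class, ...) {
  rlang::abort(message, class = paste0("multisync_error_", class), ...)
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}
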