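#' @title Stimulus-locked evoked-response analysis
#' @name evoked
#' @description
#' Epoching with pre-stimulus baseline correction, across-trial averaging,
#' Woody alignment (bounded latency correction against a template) and
#' scalar template projection, plus the vital-signs epoching modes used for
#' a single heel lance versus a train of stimuli.
NULL

#' Band-pass an EEG channel
#'
#' Zero-phase 0.5–30 Hz band-pass with a 50 Hz mains notch.
#'
#' @param ts a [signal_ts()] (rate > 100 Hz).
#' @param band pass band in Hz.
#' @param notch mains frequency in Hz (`NULL` to skip).
#' @return a filtered [signal_ts()].
#' @export
bandpass_eeg <- function(ts, band = c(0.5, 30), notch = 50) {
  stopifnot(inherits(ts, "ms_signal"))
  if (sig_rate(ts) <= 100) {
    ms_abort("sampling rate too low for EEG filtering", "argument")
  }
  v <- bandpass_zero_phase(ts$value, sig_rate(ts), band)
  if (!is.null(notch)) v <- notch_zero_phase(v, sig_rate(ts), notch)
  set_values(ts, v)
}

#' Epoch a signal around events with baseline correction
#'
#' Cuts inclusive `[-pre, +post]` epochs around each event (both endpoints
#' kept, so each trial has `round(pre*rate) + round(post*rate) + 1` samples)
#' and subtracts the per-trial mean over the baseline interval. Events whose
#' window does not fit inside the record are skipped with a warning, or
#' raise an error in strict mode.
#'
#' @param ts a [signal_ts()].
#' @param events event times in seconds, or a data frame with column
#'   `time_s`.
#' @param pre,post window half-widths in seconds.
#' @param baseline `(from, to)` interval in seconds relative to the event
#'   over which the per-trial mean is removed, taken half-open `[from, to)`
#'   so the default full pre-stimulus interval excludes the stimulus sample
#'   itself. `NULL` disables baseline correction.
#' @param strict error (instead of skip) on events too near the record edge.
#' @return a long tibble of class `ms_epochs` with columns `trial`, `time`
#'   (seconds relative to the event), `value`; attributes `rate`, `pre`,
#'   `post`, `baseline`, `events` (times actually used).
#' @export
epoch_signal <- function(ts, events, pre = 0.5, post = 1,
                         baseline = c(-pre, 0), strict = FALSE) {
  stopifnot(inherits(ts, "ms_signal"))
  times <- if (is.data.frame(events)) events$time_s else as.double(events)
  if (length(times) == 0L) ms_abort("no events supplied", "argument")
  rate <- sig_rate(ts)
  rows <- list()
  used <- numeric(0)
  for (i in seq_along(times)) {
    ep <- extract_epoch(ts, times[i], pre, post)
    if (is.null(ep)) {
      if (strict) {
        ms_abort(sprintf("event at %.3f s too near the record edge", times[i]),
          "argument")
      }
      warning(sprintf("skipping event at %.3f s: epoch outside record", times[i]))
      next
    }
    v <- ep$value
    if (!is.null(baseline)) {
      in_bl <- ep$rel >= baseline[1] & ep$rel < baseline[2]
      v <- v - mean(v[in_bl])
    }
    used <- c(used, times[i])
    rows[[length(rows) + 1L]] <-
      tibble::tibble(trial = length(used), time = ep$rel, value = v)
  }
  if (length(rows) == 0L) ms_abort("no event window fits inside the record", "argument")
  out <- dplyr::bind_rows(rows)
  attr(out, "rate") <- rate
  attr(out, "pre") <- pre
  attr(out, "post") <- post
  attr(out, "baseline") <- baseline
  attr(out, "channel") <- sig_label(ts)
  attr(out, "events") <- used
  class(out) <- c("ms_epochs", class(tibble::tibble()))
  out
}

#' @rdname epoch_signal
#' @param es a `ms_epochs`.
#' @return `epochs_matrix()` returns the trials-by-samples matrix view.
#' @export
epochs_matrix <- function(es) {
  stopifnot(inherits(es, "ms_epochs"))
  wide <- tidyr::pivot_wider(es, names_from = "time", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$trial
  m
}

#' Average epochs across trials
#'
#' @param es a `ms_epochs` with at least one trial.
#' @return the pointwise mean across trials as a [signal_ts()] whose time
#'   axis is relative to the stimulus.
#' @export
average_epochs <- function(es) {
  stopifnot(inherits(es, "ms_epochs"))
  if (nrow(es) == 0L) ms_abort("no trials to average", "argument")
  avg <- es |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$time)
  signal_ts(avg$value, rate = attr(es, "rate"), start = avg$time[1],
    label = paste0(attr(es, "channel"), " average"), units = "a.u.")
}

#' Woody alignment and template projection of a single epoch
#'
#' Finds the integer-sample shift within `±max_shift` that maximises the
#' Pearson correlation between the epoch and the shifted template (Woody
#' filtering against a fixed template), then regresses the shifted template
#' onto the epoch to obtain a scalar response magnitude. Ties are broken
#' toward the smallest absolute shift. A response whose true latency exceeds
#' the bound is assigned the boundary shift (the estimate clamps at
#' `±max_shift`).
#'
#' @param epoch a single-trial epoch: a [signal_ts()] on a stimulus-relative
#'   time axis, a one-trial `ms_epochs`, or a bare numeric vector (then
#'   `rate` and `epoch_start` are required).
#' @param template the evoked template as a [signal_ts()] at the same rate,
#'   whose `start` attribute is the support onset relative to the stimulus.
#' @param max_shift latency-correction bound in seconds (default ±100 ms).
#' @param rate,epoch_start sampling rate (Hz) and epoch start time (s),
#'   needed only for bare numeric epochs.
#' @return object of class `ms_woody`: `shift` (s), `magnitude` (scalar
#'   least-squares factor), `correlation` at the chosen shift, and `fitted`
#'   (the scaled shifted template as a [signal_ts()]).
#' @examples
#' tpl <- synthetic_template(rate = 500, support = c(0, 0.4))
#' ep <- signal_ts(c(numeric(100), tpl$value, numeric(100)),
#'   rate = 500, start = -0.2)
#' woody_align(ep, tpl, max_shift = 0.1)
#' @export
woody_align <- function(epoch, template, max_shift = 0.1,
                        rate = NULL, epoch_start = NULL) {
  stopifnot(inherits(template, "ms_signal"))
  if (inherits(epoch, "ms_epochs")) {
    if (max(epoch$trial) != 1L) {
      ms_abort("woody_align takes a single trial; filter the epoch set first",
        "argument")
    }
    rate <- attr(epoch, "rate")
    epoch_start <- -attr(epoch, "pre")
    epoch <- epoch$value
  } else if (inherits(epoch, "ms_signal")) {
    rate <- sig_rate(epoch)
    epoch_start <- sig_start(epoch)
    epoch <- epoch$value
  } else if (is.null(rate) || is.null(epoch_start)) {
    ms_abort("numeric epochs need `rate` and `epoch_start`", "argument")
  }
  if (abs(rate - sig_rate(template)) > 1e-9) {
    ms_abort("template and epoch must share one sampling rate", "argument")
  }
  m <- template$value
  L <- length(m)
  if (L > length(epoch)) ms_abort("template longer than the epoch", "argument")
  K <- round(max_shift * rate)
  offset0 <- round((sig_start(template) - epoch_start) * rate)
  if (offset0 - K < 0 || offset0 + K + L > length(epoch)) {
    ms_abort("template support must fit inside the epoch at all shifts",
      "argument")
  }
  ks <- seq.int(-K, K)
  cors <- vapply(ks, function(k) {
    stats::cor(epoch[(offset0 + k + 1):(offset0 + k + L)], m)
  }, numeric(1))
  best <- which(cors == max(cors))
  best <- best[order(abs(ks[best]), ks[best])][1]
  k <- ks[best]
  seg <- epoch[(offset0 + k + 1):(offset0 + k + L)]
  magnitude <- sum(seg * m) / sum(m^2)
  structure(
    list(
      shift = k / rate,
      magnitude = magnitude,
      correlation = cors[best],
      fitted = signal_ts(magnitude * m, rate = rate,
        start = sig_start(template) + k / rate,
        label = "fitted template", units = "a.u."),
      max_shift = max_shift
    ),
    class = "ms_woody"
  )
}

#' @export
print.ms_woody <- function(x, ...) {
  cat(sprintf(
    "<ms_woody> shift %+.1f ms (bound ±%.0f ms), magnitude %.3f, r = %.3f\n",
    1e3 * x$shift, 1e3 * x$max_shift, x$magnitude, x$correlation
  ))
  invisible(x)
}

#' Epoch 1 Hz vital-sign numerics around stimuli
#'
#' Two modes matching the two stimulus protocols: `single_lance` takes a
#' one-minute epoch from 15 s before to 45 s after the (single) lance and
#' keeps raw values; `stimulus_train` epochs from 5 s before to 10 s after
#' each stimulus and baseline-corrects by subtracting the pre-stimulus mean
#' so responses can be averaged across the train.
#'
#' @param numeric_ts a 1 Hz [signal_ts()] (heart rate or oxygen saturation).
#' @param events event times (seconds) or data frame with `time_s`.
#' @param mode `"stimulus_train"` or `"single_lance"`.
#' @param strict error on events too near the record edge.
#' @return a `ms_epochs` (see [epoch_signal()]).
#' @export
epoch_vitals <- function(numeric_ts, events,
                         mode = c("stimulus_train", "single_lance"),
                         strict = FALSE) {
  mode <- match.arg(mode)
  if (mode == "single_lance") {
    epoch_signal(numeric_ts, events, pre = 15, post = 45, baseline = NULL,
      strict = strict)
  } else {
    epoch_signal(numeric_ts, events, pre = 5, post = 10, baseline = c(-5, 0),
      strict = strict)
  }
}

#' Plot an epoch set with its across-trial average
#'
#' @param object a `ms_epochs`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ms_epochs <- function(object, ...) {
  avg <- average_epochs(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value,
    group = .data$trial)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.2) +
    ggplot2::geom_line(
      data = tibble::tibble(time = avg$time, value = avg$value, trial = 0),
      colour = "red", linewidth = 0.5
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time relative to stimulus (s)", y = "a.u.",
      title = attr(object, "channel"))
}
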