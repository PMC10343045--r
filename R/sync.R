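#' @title Synchronisation assessment
#' @name sync
#' @description
#' Two complementary assessments of event time-locking between the research
#' recorder and the vital-signs monitor: (1) marking precision, measured as
#' the delay between an event mark and the onset of the physical push-button
#' artifact it annotates on the impedance pneumograph; (2) inter-device lag,
#' measured as the shift maximising the cross-correlation between the two
#' devices' ECG recordings epoched around a common event time.
NULL

# extract an inclusive [-pre, +post] epoch around `center` on the signal's
# own time axis; sample 0 of the epoch is the grid sample nearest `center`
extract_epoch <- function(sig, center, pre, post) {
  stopifnot(inherits(sig, "ms_signal"))
  rate <- sig_rate(sig)
  i0 <- round((center - sig_start(sig)) * rate)
  k <- seq.int(-round(pre * rate), round(post * rate))
  idx <- i0 + k + 1L
  if (idx[1] < 1L || idx[length(idx)] > nrow(sig)) {
    return(NULL)
  }
  list(value = sig$value[idx], rel = k / rate, rate = rate)
}

#' Detect the onset of a push-button artifact around an event mark
#'
#' The pneumograph is epoched from `pre` seconds before to `post` seconds
#' after the event mark and baseline-corrected to the pre-mark mean. A
#' threshold is set at `threshold_fraction` (default 3%) of the minimum
#' signal value in the 1 second after the mark, and the onset is the time of
#' the earliest sample in the whole epoch at which the signal falls below
#' that threshold — negative onsets mean the physical artifact preceded the
#' (delayed) mark, which is the usual case.
#'
#' @param ip a [signal_ts()] impedance-pneumograph record.
#' @param mark_time event-mark time on the record's time axis (0 if the
#'   record is already an epoch with the mark at time 0).
#' @param threshold_fraction fraction of the post-mark minimum defining the
#'   threshold.
#' @param pre,post epoch half-widths in seconds.
#' @return onset in seconds relative to the mark (scalar), with the applied
#'   threshold attached as attribute `"threshold"`.
#' @export
detect_artifact_onset <- function(ip, mark_time = 0, threshold_fraction = 0.03,
                                  pre = 1, post = 1) {
  ep <- extract_epoch(ip, mark_time, pre, post)
  if (is.null(ep)) {
    ms_abort("epoch around the mark does not fit inside the record", "argument")
  }
  v <- ep$value - mean(ep$value[ep$rel < 0])
  after <- ep$rel > 0 & ep$rel <= 1
  post_min <- min(v[after])
  if (post_min >= 0) {
    ms_abort("no negative deflection after the mark: no artifact found",
      "no_artifact")
  }
  thr <- threshold_fraction * post_min
  below <- which(v < thr)
  if (length(below) == 0L) {
    ms_abort("signal never crosses the artifact threshold", "no_artifact")
  }
  onset <- ep$rel[below[1]]
  attr(onset, "threshold") <- thr
  onset
}

#' Per-event marking latency from push-button artifacts
#'
#' Applies [detect_artifact_onset()] at each event mark and reports the
#' latency `mark_time - onset_time` (positive when the mark trails the
#' physical press). Manual onset adjustments can be supplied through
#' `overrides`, a data frame with columns `event` (row index into `events`)
#' and `onset_s` (absolute onset time on the record's axis).
#'
#' @param ip a [signal_ts()] impedance-pneumograph record.
#' @param events data frame of event marks with column `time_s` (and
#'   optionally `label`; only `push_button` rows are used when present), or a
#'   numeric vector of mark times.
#' @inheritParams detect_artifact_onset
#' @param overrides optional data frame of per-event onset overrides.
#' @return tibble with columns `event`, `mark_s`, `onset_s`, `latency_s`.
#' @seealso [precision_stats()]
#' @export
marking_precision <- function(ip, events, threshold_fraction = 0.03,
                              overrides = NULL) {
  marks <- if (is.data.frame(events)) {
    ev <- events
    if ("label" %in% names(ev) && any(ev$label == "push_button")) {
      ev <- ev[ev$label == "push_button", , drop = FALSE]
    }
    ev$time_s
  } else {
    as.double(events)
  }
  if (length(marks) == 0L) ms_abort("no event marks supplied", "argument")
  res <- purrr::map_dfr(seq_along(marks), function(i) {
    onset_abs <- NA_real_
    if (!is.null(overrides) && i %in% overrides$event) {
      onset_abs <- overrides$onset_s[match(i, overrides$event)]
    } else {
      onset_rel <- detect_artifact_onset(ip, marks[i],
        threshold_fraction = threshold_fraction)
      onset_abs <- marks[i] + as.numeric(onset_rel)
    }
    tibble::tibble(
      event = i, mark_s = marks[i], onset_s = onset_abs,
      latency_s = marks[i] - onset_abs
    )
  })
  res
}

#' Summary statistics of marking latencies
#'
#' @param latencies numeric vector of latencies in seconds, or a data frame
#'   with column `latency_s` and optionally `session` (per-session means are
#'   then also computed).
#' @return object of class `ms_precision` with fields `per_event`, `mean`,
#'   `sd` (n-1 denominator), `min`, `max`, `n`, and `session_means` when
#'   grouping information was supplied. [generics::glance()] returns the
#'   summary as a one-row tibble, [generics::tidy()] the per-event table.
#' @examples
#' precision_stats(c(0.04, 0.1, 0.136))
#' @export
precision_stats <- function(latencies) {
  if (is.data.frame(latencies)) {
    if (!"latency_s" %in% names(latencies)) {
      ms_abort("data frame input needs a `latency_s` column", "argument")
    }
    per_event <- tibble::as_tibble(latencies)
  } else {
    per_event <- tibble::tibble(latency_s = as.double(latencies))
  }
  if (nrow(per_event) == 0L || any(!is.finite(per_event$latency_s))) {
    ms_abort("need at least one finite latency", "argument")
  }
  x <- per_event$latency_s
  session_means <- NULL
  if ("session" %in% names(per_event)) {
    session_means <- per_event |>
      dplyr::group_by(.data$session) |>
      dplyr::summarise(
        mean_latency_s = mean(.data$latency_s),
        n = dplyr::n(), .groups = "drop"
      )
  }
  structure(
    list(
      per_event = per_event,
      mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else 0,
      min = min(x), max = max(x), n = length(x),
      session_means = session_means
    ),
    class = "ms_precision"
  )
}

#' @export
print.ms_precision <- function(x, ...) {
  cat(sprintf(
    "<ms_precision> n = %d events: mean %.1f ms (sd %.1f, range %.0f-%.0f)\n",
    x$n, 1e3 * x$mean, 1e3 * x$sd, 1e3 * x$min, 1e3 * x$max
  ))
  if (!is.null(x$session_means)) {
    cat(sprintf(
      "  session means span %.0f-%.0f ms over %d sessions\n",
      1e3 * min(x$session_means$mean_latency_s),
      1e3 * max(x$session_means$mean_latency_s),
      nrow(x$session_means)
    ))
  }
  invisible(x)
}

#' Band-pass a monitor ECG channel for lag estimation
#'
#' Zero-phase 12–40 Hz band-pass that removes slow movement drift and makes
#' the monitor's inbuilt filtering comparable to the research recording's;
#' sampling rate is unchanged.
#'
#' @param ts a [signal_ts()] (rate >= 100 Hz).
#' @param band pass band in Hz.
#' @return a filtered [signal_ts()].
#' @export
preprocess_monitor_ecg <- function(ts, band = c(12, 40)) {
  stopifnot(inherits(ts, "ms_signal"))
  if (sig_rate(ts) < 100) {
    ms_abort("sampling rate too low for the 12-40 Hz band", "argument")
  }
  set_values(ts,
    bandpass_zero_phase(ts$value, sig_rate(ts), band, order_hp = 4))
}

#' Filter and down-sample a research ECG channel for lag estimation
#'
#' Zero-phase 12–40 Hz band-pass, 50 Hz notch, then anti-aliased resampling
#' to the monitor's rate so the two records can be cross-correlated sample
#' by sample.
#'
#' @inheritParams preprocess_monitor_ecg
#' @param target_rate output sampling rate in Hz (monitor ECG default 250).
#' @param notch mains frequency to notch out, Hz (`NULL` to skip).
#' @return a filtered [signal_ts()] at `target_rate`.
#' @export
preprocess_research_ecg <- function(ts, target_rate = 250, band = c(12, 40),
                                    notch = 50) {
  stopifnot(inherits(ts, "ms_signal"))
  rate <- sig_rate(ts)
  if (rate < target_rate) {
    ms_abort("input rate below the target rate", "argument")
  }
  v <- bandpass_zero_phase(ts$value, rate, band, order_hp = 4)
  if (!is.null(notch)) v <- notch_zero_phase(v, rate, notch)
  if (rate > target_rate) v <- decimate_zero_phase(v, rate, target_rate)
  signal_ts(v, rate = target_rate, start = sig_start(ts),
    label = sig_label(ts), units = sig_units(ts))
}

# bounded cross-correlation argmax between two equal-rate epochs;
# positive k means b lags a; ties resolved toward the smallest |k|
xcorr_argmax <- function(a, b, max_lag_samples) {
  a <- a - mean(a)
  b <- b - mean(b)
  n <- length(a)
  ks <- seq.int(-max_lag_samples, max_lag_samples)
  cc <- vapply(ks, function(k) {
    if (k >= 0) {
      sum(a[seq_len(n - k)] * b[seq_len(n - k) + k])
    } else {
      sum(a[seq_len(n + k) - k] * b[seq_len(n + k)])
    }
  }, numeric(1))
  best <- which(cc == max(cc))
  best <- best[order(abs(ks[best]), ks[best])][1]
  list(lag = ks[best], cc = cc, lags = ks)
}

#' Inter-device lag around one event by bounded cross-correlation
#'
#' Both ECG records (already preprocessed to a common rate) are epoched
#' `half_window` seconds either side of the event time on their own time
#' axes; the lag is the shift within `±max_lag` maximising the
#' cross-correlation of the two mean-removed epochs. Positive lag means `b`
#' lags `a`. Ties are broken toward the smallest absolute lag, which matters
#' on purely periodic signals where the correlation repeats every heartbeat.
#'
#' @param ecg_a,ecg_b [signal_ts()] records at the same sampling rate.
#' @param event_time event time in seconds (common nominal timeline).
#' @param half_window epoch half-width, seconds.
#' @param max_lag lag search bound, seconds; the default 2.5 s is well above
#'   plausible inter-device offsets while limiting heartbeat-period aliasing.
#' @return lag in seconds (scalar).
#' @export
estimate_event_lag <- function(ecg_a, ecg_b, event_time, half_window = 5,
                               max_lag = 2.5) {
  stopifnot(inherits(ecg_a, "ms_signal"), inherits(ecg_b, "ms_signal"))
  rate <- sig_rate(ecg_a)
  if (abs(rate - sig_rate(ecg_b)) > 1e-9) {
    ms_abort("both records must share one sampling rate (preprocess first)",
      "argument")
  }
  ea <- extract_epoch(ecg_a, event_time, half_window, half_window)
  eb <- extract_epoch(ecg_b, event_time, half_window, half_window)
  if (is.null(ea) || is.null(eb)) {
    ms_abort("records do not cover the full epoch around the event", "argument")
  }
  res <- xcorr_argmax(ea$value, eb$value, round(max_lag * rate))
  res$lag / rate
}

#' Session-level synchronisation offset from per-event lags
#'
#' @param lags numeric vector of per-event lags in seconds, or a data frame
#'   with column `lag_s`.
#' @return object of class `ms_lag` with fields `per_event`, `session_mean`
#'   (signed mean) and `session_abs_mean` (mean absolute lag); both are
#'   reported because a signed and an absolute per-session average answer
#'   slightly different questions about device alignment.
#' @export
session_sync_offset <- function(lags) {
  x <- if (is.data.frame(lags)) lags$lag_s else as.double(lags)
  if (length(x) == 0L || any(!is.finite(x))) {
    ms_abort("need at least one finite lag", "argument")
  }
  structure(
    list(
      per_event = tibble::tibble(event = seq_along(x), lag_s = x),
      session_mean = mean(x),
      session_abs_mean = mean(abs(x))
    ),
    class = "ms_lag"
  )
}

#' @export
print.ms_lag <- function(x, ...) {
  cat(sprintf(
    "<ms_lag> %d events: mean %.1f ms, mean |lag| %.1f ms\n",
    nrow(x$per_event), 1e3 * x$session_mean, 1e3 * x$session_abs_mean
  ))
  invisible(x)
}
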