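#' @title Breath detection and windowed respiratory rate
#' @name respiration
#' @description
#' Inter-breath intervals are computed from the impedance pneumograph after
#' cardiac-interference removal, using an adaptive amplitude-threshold breath
#' detector; respiratory rate is then computed in sliding windows as 60
#' divided by the mean inter-breath interval, with an edge-gap padding rule
#' that guards against spurious rates when a breathing pause overlaps a
#' window edge.
NULL

#' Detect R peaks on an ECG record
#'
#' Simple amplitude-based QRS picker used to estimate the instantaneous
#' cardiac frequency: band-pass to the QRS band, then local maxima above
#' half the global maximum with a refractory period.
#'
#' @param ecg a [signal_ts()].
#' @param min_rr refractory period in seconds.
#' @return numeric vector of R-peak times (seconds on the record's axis).
#' @export
detect_r_peaks <- function(ecg, min_rr = 0.25) {
  stopifnot(inherits(ecg, "ms_signal"))
  rate <- sig_rate(ecg)
  v <- if (rate > 100) bandpass_zero_phase(ecg$value, rate, c(8, 45)) else ecg$value
  if (max(abs(v)) == 0) return(numeric(0))
  thr <- 0.5 * max(v)
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  cand <- cand[v[cand] > thr]
  if (length(cand) == 0L) return(numeric(0))
  keep <- cand[1]
  for (i in cand[-1]) {
    if ((i - keep[length(keep)]) / rate >= min_rr) {
      keep <- c(keep, i)
    } else if (v[i] > v[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  ecg$time[keep]
}

#' Remove cardiac interference from an impedance pneumograph
#'
#' The pneumograph shares electrodes with the ECG, so a cardiac-frequency
#' component rides on the respiration signal. R peaks detected on the ECG
#' give the instantaneous cardiac frequency, and the pneumograph is
#' zero-phase low-pass filtered below it (cutoff = `cutoff_factor` times the
#' cardiac frequency, floored at `min_cutoff` so neonatal breathing up to
#' ~40 breaths/min is preserved). Without a usable ECG the filter falls back
#' to a fixed cutoff, with a warning.
#'
#' @param ip impedance pneumograph [signal_ts()].
#' @param ecg ECG [signal_ts()] guiding the cutoff, or `NULL`.
#' @param cutoff_factor fraction of the cardiac frequency used as cutoff.
#' @param min_cutoff lower bound on the cutoff, Hz.
#' @param fallback_cutoff fixed cutoff used when no R peaks are found, Hz.
#' @return the filtered [signal_ts()], with attributes `"cutoff_hz"` and
#'   `"cardiac_freq_hz"`.
#' @export
remove_cardiac_interference <- function(ip, ecg = NULL, cutoff_factor = 0.6,
                                        min_cutoff = 0.7,
                                        fallback_cutoff = 1.5) {
  stopifnot(inherits(ip, "ms_signal"))
  f_c <- NA_real_
  if (!is.null(ecg)) {
    r <- detect_r_peaks(ecg)
    if (length(r) >= 3) f_c <- 1 / stats::median(diff(r))
  }
  if (is.na(f_c)) {
    if (!is.null(ecg)) {
      warning("no detectable R peaks; falling back to fixed low-pass")
    }
    cutoff <- fallback_cutoff
  } else {
    cutoff <- max(min_cutoff, cutoff_factor * f_c)
  }
  out <- set_values(ip, lowpass_zero_phase(ip$value, sig_rate(ip), cutoff))
  attr(out, "cutoff_hz") <- cutoff
  attr(out, "cardiac_freq_hz") <- f_c
  out
}

#' Build an inter-breath-interval sequence from breath times
#'
#' @param breath_times strictly increasing breath times, seconds.
#' @return tibble of class `ms_ibi` with columns `breath_s` and `ibi_s`
#'   (interval since the previous breath; `NA` for the first).
#' @export
ibi_sequence <- function(breath_times) {
  breath_times <- as.double(breath_times)
  if (length(breath_times) > 1 && any(diff(breath_times) <= 0)) {
    ms_abort("breath times must be strictly increasing", "argument")
  }
  out <- tibble::tibble(
    breath_s = breath_times,
    ibi_s = c(NA_real_, diff(breath_times))
  )
  class(out) <- c("ms_ibi", class(tibble::tibble()))
  out
}

#' Adaptive-threshold breath detection
#'
#' Walks the (cleaned) pneumograph excursion by excursion. The running
#' amplitude statistic is the median of the last `n_recent` accepted
#' peak-to-trough excursions (initialised from the signal range over the
#' first `init_window` seconds). An excursion counts as a breath when it
#' rises at least `accept_frac` of that statistic above the preceding trough
#' (subject to a refractory period); keeping the acceptance gate below the
#' timing threshold lets the statistic keep tracking through sudden
#' amplitude drops such as a halving, with no missed breaths. Each breath
#' time is the rising crossing of the amplitude threshold
#' `trough + threshold_frac * excursion`, linearly interpolated between
#' samples — the threshold crossings that are marked on respiration traces.
#'
#' A flat record yields an empty sequence (apnoea is not an error).
#'
#' @param ip_clean a [signal_ts()], ideally after
#'   [remove_cardiac_interference()].
#' @param threshold_frac fraction of the excursion amplitude whose rising
#'   crossing defines the breath time.
#' @param accept_frac fraction of the running amplitude statistic an
#'   excursion must reach to count as a breath.
#' @param refractory minimum inter-breath time, seconds.
#' @param n_recent number of recent excursions in the running median.
#' @param init_window seconds used to initialise the amplitude statistic.
#' @return a `ms_ibi` (see [ibi_sequence()]).
#' @export
detect_breaths <- function(ip_clean, threshold_frac = 0.5, accept_frac = 0.25,
                           refractory = 0.3, n_recent = 5, init_window = 15) {
  stopifnot(inherits(ip_clean, "ms_signal"))
  v <- ip_clean$value
  t <- ip_clean$time
  rate <- sig_rate(ip_clean)
  init_n <- min(length(v), max(2L, round(init_window * rate)))
  amp0 <- diff(range(v[seq_len(init_n)]))
  scale <- diff(range(v))
  if (scale == 0 || amp0 < 1e-12 * max(1, max(abs(v)))) {
    return(ibi_sequence(numeric(0)))
  }
  peaks <- which(diff(sign(diff(v))) < 0) + 1L
  if (length(peaks) == 0L) return(ibi_sequence(numeric(0)))

  breaths <- numeric(0)
  amps <- numeric(0)
  search_from <- 1L
  last_breath <- -Inf
  for (p in peaks) {
    if (p <= search_from) next
    seg <- search_from:p
    trough_idx <- seg[which.min(v[seg])]
    exc <- v[p] - v[trough_idx]
    amp_est <- if (length(amps)) stats::median(amps) else amp0
    if (amp_est <= 0 || exc < accept_frac * amp_est) next
    if (t[p] - last_breath < refractory) next
    level <- v[trough_idx] + threshold_frac * exc
    cross <- which(v[trough_idx:p] >= level)[1] + trough_idx - 1L
    tc <- if (cross == trough_idx) {
      t[cross]
    } else {
      t[cross - 1L] +
        (level - v[cross - 1L]) / (v[cross] - v[cross - 1L]) / rate
    }
    breaths <- c(breaths, tc)
    amps <- utils::tail(c(amps, exc), n_recent)
    last_breath <- tc
    search_from <- p
  }
  ibi_sequence(breaths)
}

#' Windowed respiratory rate from inter-breath intervals
#'
#' Slides a `window`-second window in `step`-second increments over `span`.
#' In each window the inter-breath intervals of the breaths inside it are
#' collected; if the first (last) breath lies more than `edge_gap` seconds
#' from the window start (end), that gap is included as an additional
#' interval — this padding accounts for prolonged breathing pauses
#' overlapping the window edge, which would otherwise inflate the rate. The
#' rate is 60 divided by the mean of the augmented intervals. Windows
#' containing no breaths, or no usable interval, are flagged undefined
#' rather than given a fabricated rate.
#'
#' @param ibi a `ms_ibi` from [detect_breaths()] / [ibi_sequence()], or a
#'   numeric vector of breath times.
#' @param window window length, seconds (default 20).
#' @param step window increment, seconds (default 1).
#' @param edge_gap gap beyond which an edge interval is padded in, seconds
#'   (default 1.5, i.e. 40 breaths/min).
#' @param span `(from, to)` time range to cover; defaults to 0 up to the
#'   last breath.
#' @return tibble of class `ms_rr` with columns `window_start`,
#'   `window_center`, `n_breaths`, `rr_bpm` (`NA` when undefined),
#'   `defined`.
#' @examples
#' # steady breathing every second: 60 breaths/min in every window
#' rr <- windowed_rr(ibi_sequence(0:60), window = 20, step = 5)
#' unique(rr$rr_bpm)
#' @export
windowed_rr <- function(ibi, window = 20, step = 1, edge_gap = 1.5,
                        span = NULL) {
  if (window <= 0 || step <= 0) {
    ms_abort("`window` and `step` must be positive", "argument")
  }
  breaths <- if (inherits(ibi, "ms_ibi") || is.data.frame(ibi)) {
    ibi$breath_s
  } else {
    as.double(ibi)
  }
  if (is.null(span)) {
    span <- c(0, if (length(breaths)) max(breaths) else window)
  }
  starts <- seq(span[1], span[2] - window + 1e-12, by = step)
  if (length(starts) == 0L) starts <- span[1]
  res <- purrr::map_dfr(starts, function(s) {
    e <- s + window
    inside <- breaths[breaths >= s & breaths <= e]
    n <- length(inside)
    if (n == 0L) {
      return(tibble::tibble(window_start = s, window_center = s + window / 2,
        n_breaths = 0L, rr_bpm = NA_real_, defined = FALSE))
    }
    ibis <- diff(inside)
    lead_gap <- inside[1] - s
    trail_gap <- e - inside[n]
    if (lead_gap > edge_gap) ibis <- c(lead_gap, ibis)
    if (trail_gap > edge_gap) ibis <- c(ibis, trail_gap)
    if (length(ibis) == 0L) {
      return(tibble::tibble(window_start = s, window_center = s + window / 2,
        n_breaths = n, rr_bpm = NA_real_, defined = FALSE))
    }
    tibble::tibble(window_start = s, window_center = s + window / 2,
      n_breaths = n, rr_bpm = 60 / mean(ibis), defined = TRUE)
  })
  attr(res, "window") <- window
  attr(res, "step") <- step
  attr(res, "edge_gap") <- edge_gap
  class(res) <- c("ms_rr", class(tibble::tibble()))
  res
}

#' Plot a windowed respiratory-rate series
#'
#' @param object a `ms_rr`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ms_rr <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$window_center, y = .data$rr_bpm)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.5, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "respiratory rate (breaths/min)")
}
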