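#' @title Synthetic dual-device session generators
#' @name simgen
#' @description
#' Generators for synthetic physiological recordings with known ground truth:
#' ECG (sum-of-Gaussian-bump morphology), impedance-pneumograph respiration
#' (raised-cosine excursions), stimulus-evoked EEG (template insertions in
#' noise) and the push-button artifact used to measure marking precision.
#' [simulate_session()] composes them into a two-device recording with a
#' configurable inter-device clock offset and marking-latency model, which is
#' the ground-truthed input for every analysis in the package.
NULL

# ---- analytic source waveforms -------------------------------------------
# Each source is an analytic function of true time so that both devices can
# sample the identical underlying process on their own clock grids (exact
# sub-sample inter-device offsets, no intermediate resampling error).

# ECG as Gaussian bumps per beat: dominant R, smaller P and T deflections.
ecg_waveform <- function(t, r_times, amplitude = 1) {
  comp <- list(
    c(delay = 0, sd = 0.012, amp = 1),
    c(delay = -0.16, sd = 0.025, amp = 0.15),
    c(delay = 0.22, sd = 0.05, amp = 0.30)
  )
  v <- numeric(length(t))
  for (b in r_times) {
    for (cc in comp) {
      ctr <- b + cc[["delay"]]
      lo <- findInterval(ctr - 5 * cc[["sd"]], t) + 1L
      hi <- findInterval(ctr + 5 * cc[["sd"]], t)
      if (hi >= lo) {
        idx <- lo:hi
        v[idx] <- v[idx] +
          cc[["amp"]] * exp(-((t[idx] - ctr)^2) / (2 * cc[["sd"]]^2))
      }
    }
  }
  amplitude * v
}

# one smooth raised-cosine respiratory excursion per breath onset
resp_waveform <- function(t, breath_times, width = 0.9, amplitude = 1) {
  v <- numeric(length(t))
  for (b in breath_times) {
    lo <- findInterval(b, t) + 1L
    hi <- findInterval(b + width, t)
    if (hi >= lo) {
      idx <- lo:hi
      v[idx] <- v[idx] +
        amplitude * 0.5 * (1 - cos(2 * pi * (t[idx] - b) / width))
    }
  }
  v
}

# negative-going push-button deflection: fast linear attack to -depth over
# `attack` seconds, then half-cosine recovery to baseline at `width`
pushbutton_shape <- function(u, depth, width, attack = 0.02) {
  out <- numeric(length(u))
  rise <- u >= 0 & u < attack
  out[rise] <- -depth * u[rise] / attack
  rec <- u >= attack & u <= width
  out[rec] <- -depth * 0.5 * (1 + cos(pi * (u[rec] - attack) / (width - attack)))
  out
}

# beat schedule from a heart-rate profile (bpm scalar or function of time),
# with multiplicative log-normal beat-to-beat variability
gen_beats <- function(duration, heart_rate, hrv_sd = 0) {
  hr_at <- if (is.function(heart_rate)) heart_rate else function(t) heart_rate
  hr0 <- hr_at(0)
  if (hr0 <= 30 || hr0 >= 250) {
    ms_abort("heart rate must lie within (30, 250) bpm", "argument")
  }
  beats <- numeric(0)
  t <- 0.4 * 60 / hr0
  while (t < duration) {
    beats <- c(beats, t)
    rr <- 60 / hr_at(t)
    if (hrv_sd > 0) rr <- rr * exp(stats::rnorm(1, -hrv_sd^2 / 2, hrv_sd))
    t <- t + rr
  }
  beats
}

#' Simulate an ECG channel
#'
#' Quasi-periodic ECG built from Gaussian bumps (dominant R wave, smaller P
#' and T), with optional multiplicative beat-to-beat variability. The true
#' R-peak times are returned as the `"r_peaks"` attribute of the signal.
#'
#' @param duration record length in seconds (> 0).
#' @param heart_rate heart rate in beats per minute, a scalar or a function
#'   of time; must lie within (30, 250).
#' @param rate sampling rate in Hz.
#' @param hrv_sd sd of log inter-beat-interval variability (0 = metronomic).
#' @param amplitude R-wave amplitude in signal units.
#' @param seed optional integer seed.
#' @return a [signal_ts()] with attribute `"r_peaks"` (true R-peak times, s).
#' @examples
#' ecg <- simulate_ecg(10, heart_rate = 120, rate = 250)
#' length(attr(ecg, "r_peaks"))
#' @export
simulate_ecg <- function(duration, heart_rate = 120, rate = 250, hrv_sd = 0,
                         amplitude = 1, seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) {
    ms_abort("`duration` must be positive", "argument")
  }
  with_seed_if(seed, {
    beats <- gen_beats(duration, heart_rate, hrv_sd)
    t <- (seq_len(round(duration * rate)) - 1) / rate
    sig <- signal_ts(ecg_waveform(t, beats, amplitude),
      rate = rate, label = "ECG", units = "a.u.")
    attr(sig, "r_peaks") <- beats
    sig
  })
}

#' Simulate an impedance-pneumograph channel
#'
#' One raised-cosine excursion per breath time, plus an optional additive
#' cardiac-frequency component (the cardiac interference visible on real IP,
#' since the pneumograph shares the ECG electrodes) and white noise.
#'
#' @param duration record length, seconds.
#' @param breath_times breath onset times within `[0, duration]`.
#' @param rate sampling rate in Hz (monitor default 62.5).
#' @param cardiac_gain amplitude of the cardiac interference component.
#' @param cardiac_freq cardiac frequency in Hz used for the interference
#'   (a pure tone); required when `cardiac_gain > 0`.
#' @param noise_sd sd of additive white noise.
#' @param width excursion width in seconds.
#' @param amplitude excursion amplitude.
#' @param seed optional integer seed.
#' @return a [signal_ts()].
#' @export
simulate_ip <- function(duration, breath_times, rate = 62.5,
                        cardiac_gain = 0, cardiac_freq = 2,
                        noise_sd = 0, width = 0.9, amplitude = 1,
                        seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) {
    ms_abort("`duration` must be positive", "argument")
  }
  if (length(breath_times) &&
    (min(breath_times) < 0 || max(breath_times) > duration)) {
    ms_abort("`breath_times` must lie within [0, duration]", "argument")
  }
  with_seed_if(seed, {
    t <- (seq_len(round(duration * rate)) - 1) / rate
    v <- resp_waveform(t, breath_times, width, amplitude)
    if (cardiac_gain > 0) v <- v + cardiac_gain * sin(2 * pi * cardiac_freq * t)
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    signal_ts(v, rate = rate, label = "IP", units = "a.u.")
  })
}

#' Inject a push-button artifact into a pneumograph record
#'
#' Adds a negative-going deflection that starts at the sample
#' `floor((press_time - start) * rate)`, drops to `-depth` with a fast linear
#' attack and recovers over `width` seconds — the artifact a push button
#' pressed onto the shared ECG electrodes leaves on the impedance
#' pneumograph.
#'
#' @param ip a [signal_ts()] pneumograph record.
#' @param press_time press time in seconds on the record's time axis.
#' @param depth deflection depth in signal units (0 leaves the record
#'   untouched).
#' @param width total artifact duration, seconds.
#' @param attack attack time to reach `-depth`, seconds.
#' @return a copy of `ip` with the deflection added; attributes
#'   `"onset_index"` (0-based sample index of artifact start) and
#'   `"onset_time"` record the ground truth.
#' @export
inject_pushbutton_artifact <- function(ip, press_time, depth = 1,
                                       width = 0.5, attack = 0.02) {
  stopifnot(inherits(ip, "ms_signal"))
  rate <- sig_rate(ip)
  start <- sig_start(ip)
  if (press_time < start || press_time > start + sig_duration(ip)) {
    ms_abort("`press_time` must lie inside the record", "argument")
  }
  i0 <- floor((press_time - start) * rate)
  u <- (seq_len(nrow(ip)) - 1 - i0) / rate
  out <- set_values(ip, ip$value + pushbutton_shape(u, depth, width, attack))
  attr(out, "onset_index") <- i0
  attr(out, "onset_time") <- start + i0 / rate
  out
}

#' Synthetic evoked-response template
#'
#' A damped biphasic waveform (positive then negative deflection over
#' 0–0.7 s after the stimulus, unit peak amplitude) used as the default
#' template for evoked-response insertion and Woody alignment. Any
#' user-supplied waveform can be used in its place; this synthetic shape only
#' stands in for templates whose coefficients are not distributed with the
#' package.
#'
#' @param rate sampling rate in Hz.
#' @param support `(from, to)` support in seconds relative to the stimulus.
#' @return a [signal_ts()] with `start = support[1]`.
#' @export
synthetic_template <- function(rate = 2000, support = c(0, 0.7)) {
  t <- seq(support[1], support[2], by = 1 / rate)
  w <- exp(-((t - 0.28)^2) / (2 * 0.05^2)) -
    0.85 * exp(-((t - 0.45)^2) / (2 * 0.07^2))
  w <- w / max(abs(w))
  signal_ts(w, rate = rate, start = support[1],
    label = "template", units = "a.u.")
}

#' Simulate a stimulus-evoked EEG channel
#'
#' Background Gaussian noise plus one copy of the template inserted at each
#' stimulus time (with optional per-trial latency jitter and amplitude
#' scaling). The jitters and scales actually drawn are stored as attributes
#' `"jitter"` and `"scales"` — the ground truth for alignment recovery.
#'
#' @param duration record length, seconds.
#' @param stimulus_times stimulus onsets, seconds, strictly increasing.
#' @param template evoked template, a [signal_ts()] whose `start` is the
#'   template support onset relative to the stimulus.
#' @param jitter_sd sd of per-trial latency jitter, seconds.
#' @param amplitude_scales per-trial amplitude scale(s), recycled.
#' @param noise_sd sd of background noise.
#' @param rate sampling rate in Hz.
#' @param seed optional integer seed.
#' @return a [signal_ts()] with attributes `"jitter"` and `"scales"`.
#' @export
simulate_eeg <- function(duration, stimulus_times,
                         template = synthetic_template(),
                         jitter_sd = 0, amplitude_scales = 1,
                         noise_sd = 0, rate = 2000, seed = NULL) {
  stopifnot(inherits(template, "ms_signal"))
  stimulus_times <- sort(stimulus_times)
  supp_len <- sig_duration(template)
  if (length(stimulus_times) > 1 && min(diff(stimulus_times)) <= supp_len) {
    ms_abort("template insertions overlap: inter-stimulus interval too short",
      "argument")
  }
  with_seed_if(seed, {
    n <- round(duration * rate)
    t <- (seq_len(n) - 1) / rate
    v <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    k <- length(stimulus_times)
    jit <- if (jitter_sd > 0) stats::rnorm(k, 0, jitter_sd) else numeric(k)
    scl <- rep_len(amplitude_scales, k)
    for (i in seq_len(k)) {
      ctr <- stimulus_times[i] + jit[i]
      # epsilon keeps a support edge that falls exactly on a grid sample in
      lo <- findInterval(ctr + sig_start(template) - 1e-12, t) + 1L
      hi <- findInterval(ctr + sig_start(template) + supp_len + 1e-12, t)
      if (hi >= lo) {
        idx <- lo:hi
        ins <- stats::approx(template$time + ctr, template$value,
          xout = t[idx], yleft = 0, yright = 0)$y
        v[idx] <- v[idx] + scl[i] * ins
      }
    }
    sig <- signal_ts(v, rate = rate, label = "EEG", units = "uV")
    attr(sig, "jitter") <- jit
    attr(sig, "scales") <- scl
    sig
  })
}

#' Session configuration for the dual-device simulator
#'
#' Defaults follow the acquisition set-up the package models: a research
#' recorder sampling EEG and ECG at 2000 Hz, and a vital-signs monitor
#' delivering ECG at 250 Hz, impedance pneumography at 62.5 Hz,
#' photoplethysmography at 125 Hz and 1 Hz heart-rate / oxygen-saturation
#' numerics. The monitor runs on its own clock (`offset` seconds ahead of
#' true time) and stamps events with a truncated-normal marking latency
#' (default mean 105 ms, sd 19 ms); the research path stamps with
#' sub-millisecond delay.
#'
#' @param duration session length, seconds.
#' @param offset inter-device clock offset in seconds (monitor minus true).
#' @param heart_rate heart rate in bpm (neonatal default 150).
#' @param hrv_sd beat-to-beat variability (sd of log RR).
#' @param breath_period breathing period in seconds (neonatal default 1.5 s,
#'   40 breaths/min); used when `breath_times` is `NULL`.
#' @param breath_times explicit breath schedule, seconds.
#' @param breath_width,breath_amplitude excursion shape parameters.
#' @param stimulus_times visual-stimulus onsets, seconds.
#' @param press_times push-button press times, seconds.
#' @param press_depth,press_width push-button artifact shape.
#' @param cardiac_gain cardiac interference gain on the pneumograph.
#' @param ip_noise_sd,eeg_noise_sd,ecg_noise_sd additive noise levels.
#' @param eeg_template,eeg_jitter_sd,eeg_amplitude evoked-response insertion.
#' @param monitor_latency_mean,monitor_latency_sd monitor marking latency.
#' @param research_clock research-device clock model.
#' @param channels which channels to synthesise.
#' @param rates named list of per-channel sampling rates in Hz.
#' @return a named list of class `ms_session_config`.
#' @export
session_config <- function(duration = 60, offset = 0,
                           heart_rate = 150, hrv_sd = 0.03,
                           breath_period = 1.5, breath_times = NULL,
                           breath_width = 0.9, breath_amplitude = 1,
                           stimulus_times = numeric(0),
                           press_times = numeric(0),
                           press_depth = 1, press_width = 0.5,
                           cardiac_gain = 0,
                           ip_noise_sd = 0, eeg_noise_sd = 0, ecg_noise_sd = 0,
                           eeg_template = synthetic_template(),
                           eeg_jitter_sd = 0, eeg_amplitude = 1,
                           monitor_latency_mean = 0.105,
                           monitor_latency_sd = 0.019,
                           research_clock = research_clock_default(),
                           channels = c(
                             "research_ecg", "research_eeg", "monitor_ecg",
                             "ip", "ppg", "hr", "spo2"
                           ),
                           rates = list(
                             research_eeg = 2000, research_ecg = 2000,
                             monitor_ecg = 250, ip = 62.5, ppg = 125,
                             numerics = 1
                           )) {
  if (any(unlist(rates) <= 0)) ms_abort("all rates must be positive", "argument")
  cfg <- as.list(environment())
  class(cfg) <- "ms_session_config"
  cfg
}

#' Simulate a complete dual-device recording session
#'
#' Generates the shared physiological source (beats, breaths, evoked
#' responses), samples it on the research grid (true clock) and on the
#' monitor grid (clock shifted by `offset`, channels passed through an
#' approximation of the monitor's inbuilt band-pass), injects push-button
#' artifacts, and stamps every stimulus and press onto both timelines via
#' [bridge_trigger()]. Ground truth sufficient to score every downstream
#' analysis is returned in `$truth`.
#'
#' @param config a [session_config()].
#' @param seed optional integer seed; a fixed seed gives bit-identical
#'   sessions.
#' @return object of class `ms_session`: lists `research` and `monitor` of
#'   [signal_ts()] channels, tibbles `research_events` / `monitor_events`
#'   (columns `label`, `time_s`, `device`), and `truth` with elements
#'   `stimulus_times`, `press_times`, `breath_times`, `r_peak_times`,
#'   `inter_device_offset`, `per_event_marking_latency`, `event_labels`.
#' @examples
#' s <- simulate_session(session_config(duration = 20, press_times = 10), seed = 1)
#' names(s$monitor)
#' @export
simulate_session <- function(config = session_config(), seed = NULL) {
  stopifnot(inherits(config, "ms_session_config"))
  cfg <- config
  with_seed_if(seed, {
    dur <- cfg$duration
    beats <- gen_beats(dur, cfg$heart_rate, cfg$hrv_sd)
    breaths <- cfg$breath_times %||%
      seq(0.5 * cfg$breath_period, dur - cfg$breath_width, by = cfg$breath_period)

    monitor_clock <- clock_model(
      offset = cfg$offset,
      latency_mean = cfg$monitor_latency_mean,
      latency_sd = cfg$monitor_latency_sd
    )

    # IP source content as a function of true time (breaths + interference +
    # press artifacts), so both the truth and the monitor samples agree
    cardiac_freq <- if (length(beats) > 1) 1 / stats::median(diff(beats)) else 2
    ip_content <- function(t) {
      v <- resp_waveform(t, breaths, cfg$breath_width, cfg$breath_amplitude)
      if (cfg$cardiac_gain > 0) {
        v <- v + cfg$cardiac_gain * sin(2 * pi * cardiac_freq * t)
      }
      for (p in cfg$press_times) {
        v <- v + pushbutton_shape(t - p, cfg$press_depth, cfg$press_width)
      }
      v
    }

    research <- list()
    monitor <- list()
    grid <- function(rate) (seq_len(round(dur * rate)) - 1) / rate

    if ("research_ecg" %in% cfg$channels) {
      t <- grid(cfg$rates$research_ecg)
      v <- ecg_waveform(t, beats)
      if (cfg$ecg_noise_sd > 0) v <- v + stats::rnorm(length(v), 0, cfg$ecg_noise_sd)
      research$ecg <- signal_ts(v, cfg$rates$research_ecg,
        label = "ECG", units = "a.u.")
    }
    if ("research_eeg" %in% cfg$channels) {
      research$eeg <- simulate_eeg(dur, cfg$stimulus_times,
        template = cfg$eeg_template, jitter_sd = cfg$eeg_jitter_sd,
        amplitude_scales = cfg$eeg_amplitude, noise_sd = cfg$eeg_noise_sd,
        rate = cfg$rates$research_eeg
      )
    }

    # monitor channels: the same analytic source sampled on the monitor's
    # clock grid (axis time = true time + offset), then the monitor's nominal
    # inbuilt filter — an approximation of filtering that cannot be disabled
    mon_signal <- function(content, rate, label, units = "a.u.", band = NULL) {
      tt <- grid(rate) # true times of the monitor samples
      v <- content(tt)
      if (!is.null(band)) v <- bandpass_zero_phase(v, rate, band)
      signal_ts(v, rate, start = cfg$offset, label = label, units = units)
    }
    if ("monitor_ecg" %in% cfg$channels) {
      monitor$ecg <- mon_signal(function(t) ecg_waveform(t, beats),
        cfg$rates$monitor_ecg, "ECG", band = c(0.5, 40))
    }
    if ("ip" %in% cfg$channels) {
      t <- grid(cfg$rates$ip)
      v <- ip_content(t)
      if (cfg$ip_noise_sd > 0) v <- v + stats::rnorm(length(v), 0, cfg$ip_noise_sd)
      monitor$ip <- signal_ts(v, cfg$rates$ip, start = cfg$offset,
        label = "IP", units = "a.u.")
    }
    if ("ppg" %in% cfg$channels) {
      monitor$ppg <- mon_signal(
        function(t) {
          v <- numeric(length(t))
          for (b in beats + 0.2) {
            idx <- which(abs(t - b) < 0.4)
            v[idx] <- v[idx] + exp(-((t[idx] - b)^2) / (2 * 0.08^2))
          }
          v
        },
        cfg$rates$ppg, "PPG"
      )
    }
    if ("hr" %in% cfg$channels && length(beats) > 1) {
      rrs <- diff(beats)
      hr_fun <- stats::approxfun(beats[-1], 60 / rrs, rule = 2)
      monitor$hr <- mon_signal(function(t) hr_fun(t),
        cfg$rates$numerics, "HR", units = "bpm")
    }
    if ("spo2" %in% cfg$channels) {
      monitor$spo2 <- mon_signal(function(t) rep(97, length(t)),
        cfg$rates$numerics, "SpO2", units = "%")
    }

    ev_times <- c(cfg$stimulus_times, cfg$press_times)
    ev_labels <- c(
      rep("visual", length(cfg$stimulus_times)),
      rep("push_button", length(cfg$press_times))
    )
    ord <- order(ev_times)
    ev_times <- ev_times[ord]
    ev_labels <- ev_labels[ord]
    marks <- if (length(ev_times)) {
      bridge_trigger(ev_times, cfg$research_clock, monitor_clock,
        labels = ev_labels)
    } else {
      tibble::tibble(event = integer(), label = character(),
        device = character(), time_s = double(), latency_s = double())
    }

    structure(
      list(
        research = research,
        monitor = monitor,
        research_events = marks[marks$device == "research",
          c("label", "time_s", "device")],
        monitor_events = marks[marks$device == "monitor",
          c("label", "time_s", "device")],
        truth = list(
          stimulus_times = cfg$stimulus_times,
          press_times = cfg$press_times,
          breath_times = breaths,
          r_peak_times = beats,
          inter_device_offset = cfg$offset,
          per_event_marking_latency = marks$latency_s[marks$device == "monitor"],
          event_labels = ev_labels,
          eeg_jitter = if (!is.null(research$eeg)) attr(research$eeg, "jitter")
        ),
        config = cfg
      ),
      class = "ms_session"
    )
  })
}

#' @export
print.ms_session <- function(x, ...) {
  cat(sprintf(
    "<ms_session> %.1f s; research: %s; monitor: %s; %d events; offset %g s\n",
    x$config$duration,
    paste(names(x$research), collapse = ", "),
    paste(names(x$monitor), collapse = ", "),
    nrow(x$monitor_events), x$truth$inter_device_offset
  ))
  invisible(x)
}
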