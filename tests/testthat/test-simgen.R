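test_that("simulated ECG has one R peak per beat on the expected grid", {
  ecg <- simulate_ecg(60, heart_rate = 120, rate = 250)
  r <- attr(ecg, "r_peaks")
  expect_true(abs(length(r) - 120) <= 1)
  # returned peak times agree with an exhaustive local-maximum scan
  found <- oracle_peaks(ecg$value, min_height = 0.5)
  expect_length(found, length(r))
  expect_lt(max(abs(ecg$time[found] - r)), 1 / 250)
  # sample count convention
  expect_identical(nrow(simulate_ecg(10, 120, 250)), 2500L)
  expect_error(simulate_ecg(-1, 120, 250), class = "multisync_error_argument")
  expect_error(simulate_ecg(10, heart_rate = 20),
    class = "multisync_error_argument")
})

test_that("pneumograph generator produces one excursion per breath", {
  flat <- simulate_ip(10, numeric(0), rate = 62.5)
  expect_true(all(flat$value == 0))
  breaths <- seq(1, 59, by = 2)
  ip <- simulate_ip(60, breaths, rate = 62.5)
  # count excursions by threshold crossing at half amplitude
  up <- diff(ip$value > 0.5) == 1
  expect_identical(sum(up), length(breaths))
  expect_error(simulate_ip(10, breath_times = 11),
    class = "multisync_error_argument")
  # seeded noise is bit-identical across calls
  a <- simulate_ip(20, breaths[breaths < 20], noise_sd = 0.1, seed = 9)
  b <- simulate_ip(20, breaths[breaths < 20], noise_sd = 0.1, seed = 9)
  expect_identical(a$value, b$value)
})

test_that("push-button artifact starts on the documented sample", {
  ip <- simulate_ip(30, numeric(0), rate = 62.5)
  out <- inject_pushbutton_artifact(ip, press_time = 12.3456, depth = 2)
  expect_identical(attr(out, "onset_index"), floor(12.3456 * 62.5))
  expect_equal(min(out$value), -2, tolerance = 0.05)
  # zero depth leaves the record untouched
  same <- inject_pushbutton_artifact(ip, 12.3456, depth = 0)
  expect_equal(same$value, ip$value)
  expect_error(inject_pushbutton_artifact(ip, press_time = 31),
    class = "multisync_error_argument")
  # end-to-end: the onset detector recovers the press within one sample
  onset <- detect_artifact_onset(out, mark_time = 12.3456 + 0.1)
  onset_abs <- 12.3456 + 0.1 + as.numeric(onset)
  expect_lt(abs(onset_abs - 12.3456), 1 / 62.5 + 1e-9)
})

test_that("evoked EEG inserts the template exactly at zero noise", {
  tpl <- synthetic_template(rate = 500, support = c(0, 0.7))
  eeg <- simulate_eeg(20, 10, template = tpl, rate = 500)
  es <- epoch_signal(eeg, 10, pre = 0.5, post = 1, baseline = NULL)
  m <- epochs_matrix(es)
  rel <- seq(-0.5, 1, by = 1 / 500)
  tv <- stats::approx(tpl$time, tpl$value, xout = rel, yleft = 0, yright = 0)$y
  expect_equal(drop(m), tv, tolerance = 1e-9, ignore_attr = TRUE)
  # per-trial jitter is recovered by Woody alignment within one sample
  stim <- seq(5, 35, by = 3)
  eeg2 <- simulate_eeg(40, stim, template = tpl, jitter_sd = 0.02,
    rate = 500, seed = 3)
  jit <- attr(eeg2, "jitter")
  es2 <- epoch_signal(eeg2, stim, pre = 0.5, post = 1, baseline = NULL)
  for (i in seq_along(stim)) {
    w <- woody_align(dplyr::filter(es2, trial == i) |>
      (\(d) signal_ts(d$value, 500, start = -0.5))(), tpl, max_shift = 0.1)
    expect_lt(abs(w$shift - jit[i]), 1 / 500 + 1e-9)
  }
  expect_error(simulate_eeg(20, c(5, 5.2), template = tpl, rate = 500),
    class = "multisync_error_argument")
})

test_that("averaging many noisy trials approaches the inserted template", {
  tpl <- synthetic_template(rate = 500, support = c(0, 0.7))
  stim <- seq(5, 5 + 99 * 2, by = 2)
  eeg <- simulate_eeg(max(stim) + 5, stim, template = tpl, noise_sd = 1,
    rate = 500, seed = 6)
  avg <- average_epochs(epoch_signal(eeg, stim, pre = 0.5, post = 1,
    baseline = NULL))
  tv <- stats::approx(tpl$time, tpl$value, xout = avg$time,
    yleft = 0, yright = 0)$y
  expect_gt(stats::cor(avg$value, tv), 0.95)
})

test_that("sessions are deterministic under a fixed seed", {
  cfg <- session_config(duration = 20, stimulus_times = c(5, 8),
    press_times = 15, ip_noise_sd = 0.01, eeg_noise_sd = 1)
  s1 <- simulate_session(cfg, seed = 7)
  s2 <- simulate_session(cfg, seed = 7)
  for (ch in names(s1$research)) {
    expect_identical(s1$research[[ch]]$value, s2$research[[ch]]$value)
  }
  for (ch in names(s1$monitor)) {
    expect_identical(s1$monitor[[ch]]$value, s2$monitor[[ch]]$value)
  }
  expect_identical(s1$monitor_events, s2$monitor_events)
  expect_identical(s1$truth, s2$truth)
})

test_that("zero-latency zero-offset clocks give identical event timelines", {
  cfg <- session_config(duration = 20, stimulus_times = c(5, 10), offset = 0,
    monitor_latency_mean = 0, monitor_latency_sd = 0,
    research_clock = clock_model(), channels = "ip")
  s <- simulate_session(cfg, seed = 1)
  expect_equal(s$research_events$time_s, s$monitor_events$time_s)
  expect_equal(s$research_events$time_s, c(5, 10))
})

test_that("session truth is sufficient to score the generators", {
  cfg <- session_config(duration = 30, press_times = c(10, 20),
    stimulus_times = 25, offset = 0.15)
  s <- simulate_session(cfg, seed = 2)
  tr <- s$truth
  expect_identical(tr$inter_device_offset, 0.15)
  expect_length(tr$per_event_marking_latency, 3L)
  expect_true(all(diff(tr$breath_times) > 0))
  expect_true(all(diff(tr$r_peak_times) > 0))
  # monitor marks = true time + offset + drawn latency
  ev_true <- sort(c(cfg$press_times, cfg$stimulus_times))
  expect_equal(s$monitor_events$time_s,
    ev_true + 0.15 + tr$per_event_marking_latency)
})

test_that("both devices sample the same beat sequence", {
  cfg <- session_config(duration = 30, offset = 0.2, hrv_sd = 0.05,
    channels = c("research_ecg", "monitor_ecg"))
  s <- simulate_session(cfg, seed = 8)
  a <- preprocess_research_ecg(s$research$ecg)
  b <- preprocess_monitor_ecg(s$monitor$ecg)
  lag <- estimate_event_lag(a, b, 15)
  expect_lt(abs(lag - 0.2), 1 / 250 + 1e-9)
})
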