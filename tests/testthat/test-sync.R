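test_that("artifact onset is found where the signal crosses the threshold", {
  # negative pulse from -0.1 s before the mark to +0.5 s after: the onset is
  # forced to -0.100 s and the threshold to 3% of the corrected post-mark
  # minimum (the pre-mark mean already contains 0.1 s of the pulse)
  rate <- 1000
  t <- seq(-1.5, 1.5, by = 1 / rate)
  v <- ifelse(t >= -0.1 & t <= 0.5, -1, 0)
  sig <- signal_ts(v, rate, start = -1.5)
  onset <- detect_artifact_onset(sig, mark_time = 0)
  expect_equal(as.numeric(onset), -0.1, tolerance = 1e-9)
  bl <- mean(v[t >= -1 & t < 0]) # pre-mark mean over the extracted epoch
  expect_equal(attr(onset, "threshold"), 0.03 * (-1 - bl), tolerance = 1e-6)
  # latency convention: mark minus onset is positive when the artifact leads
  expect_equal(0 - as.numeric(onset), 0.1)
})

test_that("onset detection is translation-equivariant", {
  rate <- 250
  t <- seq(0, 6, by = 1 / rate)
  v <- ifelse(t >= 2.9 & t <= 3.4, -1, 0) # pulse 0.1 s before the mark at 3
  for (shift in c(0, 1.7, 3.21)) {
    sig <- signal_ts(v, rate, start = 10 + shift)
    onset <- detect_artifact_onset(sig, mark_time = 13 + shift)
    sig0 <- signal_ts(v, rate, start = 10)
    onset0 <- detect_artifact_onset(sig0, mark_time = 13)
    expect_equal(as.numeric(onset), as.numeric(onset0), tolerance = 1e-9)
    expect_lt(abs(as.numeric(onset0) - (-0.1)), 1 / rate + 1e-9)
  }
})

test_that("a record with no negative deflection raises a no-artifact error", {
  sig <- signal_ts(rep(2, 601), 250, start = -1.2)
  expect_error(detect_artifact_onset(sig, 0),
    class = "multisync_error_no_artifact")
})

test_that("precision statistics summarise latencies conventionally", {
  ps <- precision_stats(c(0.1, 0.1, 0.1))
  expect_equal(ps$mean, 0.1)
  expect_equal(ps$sd, 0)
  ps2 <- precision_stats(c(0.04, 0.136))
  expect_equal(ps2$min, 0.04)
  expect_equal(ps2$max, 0.136)
  expect_equal(ps2$sd, sd(c(0.04, 0.136))) # n-1 denominator
  expect_error(precision_stats(numeric(0)), class = "multisync_error_argument")
  # grouped input yields per-session means and tidy/glance views
  df <- data.frame(latency_s = c(0.1, 0.12, 0.09, 0.11),
    session = c(1, 1, 2, 2))
  ps3 <- precision_stats(df)
  expect_equal(sort(ps3$session_means$mean_latency_s), c(0.10, 0.11))
  expect_identical(nrow(tidy(ps3)), 4L)
  expect_equal(glance(ps3)$n_events, 4)
})

test_that("manual onset overrides replace detected onsets", {
  ip <- simulate_ip(30, numeric(0), rate = 62.5)
  ip <- inject_pushbutton_artifact(ip, 10, depth = 1)
  ip <- inject_pushbutton_artifact(ip, 20, depth = 1)
  res <- marking_precision(ip, c(10.1, 20.1),
    overrides = data.frame(event = 2, onset_s = 20.02))
  expect_equal(res$latency_s[2], 20.1 - 20.02)
  expect_lt(abs(res$latency_s[1] - 0.1), 2 / 62.5)
})

test_that("monitor ECG band-pass has the specified pass and stop behaviour", {
  rate <- 250
  expect_lt(filter_gain(preprocess_monitor_ecg, 0.01, rate) /
    1, 1e-3) # near-DC
  g25 <- filter_gain(preprocess_monitor_ecg, 25, rate)
  expect_gt(g25, 0.9)
  expect_lt(g25, 1.1)
  expect_lt(filter_gain(preprocess_monitor_ecg, 5, rate), 0.1)
  # DC input is annihilated away from the record edges
  dc <- preprocess_monitor_ecg(signal_ts(rep(1, 5000), rate))
  expect_lt(max(abs(dc$value[1250:3750])), 1e-6)
  # linearity: filtering a sum equals the sum of filtered parts
  t <- (0:4999) / rate
  x1 <- signal_ts(sin(2 * pi * 20 * t), rate)
  x2 <- signal_ts(cos(2 * pi * 30 * t), rate)
  xs <- signal_ts(x1$value + x2$value, rate)
  expect_equal(preprocess_monitor_ecg(xs)$value,
    preprocess_monitor_ecg(x1)$value + preprocess_monitor_ecg(x2)$value,
    tolerance = 1e-9)
  expect_error(preprocess_monitor_ecg(signal_ts(rnorm(100), 50)),
    class = "multisync_error_argument")
})

test_that("research ECG preprocessing notches mains and resamples to 250 Hz", {
  rate <- 2000
  t <- (0:(10 * rate - 1)) / rate
  s50 <- signal_ts(sin(2 * pi * 50 * t), rate)
  out <- preprocess_research_ecg(s50)
  expect_equal(sig_rate(out), 250)
  expect_equal(nrow(out), 2500)
  mid <- (nrow(out) %/% 4):(3 * nrow(out) %/% 4)
  expect_lt(max(abs(out$value[mid])), 0.05)
  # filtering involves no randomness
  v <- withr::with_seed(1, rnorm(2 * rate))
  o1 <- preprocess_research_ecg(signal_ts(v, rate))
  o2 <- preprocess_research_ecg(signal_ts(v, rate))
  expect_identical(o1$value, o2$value)
})

test_that("lag estimation matches a brute-force cross-correlation oracle", {
  ecg <- simulate_ecg(30, 150, 2000, hrv_sd = 0.03, seed = 2)
  a <- preprocess_research_ecg(ecg)
  # identical records: zero lag
  expect_equal(estimate_event_lag(a, a, 15), 0)
  # a pure 25-sample delay at 250 Hz
  b <- signal_ts(c(rep(0, 25), a$value[1:(nrow(a) - 25)]), 250)
  expect_equal(estimate_event_lag(a, b, 15), 0.1)
  ka <- extract_epochs_for_test(a, 15)
  kb <- extract_epochs_for_test(b, 15)
  expect_identical(round(estimate_event_lag(a, b, 15) * 250),
    oracle_lag_samples(ka, kb, round(2.5 * 250)))
  # antisymmetry on noise-free inputs
  expect_equal(estimate_event_lag(a, b, 15), -estimate_event_lag(b, a, 15))
  expect_error(estimate_event_lag(a, b, 2), class = "multisync_error_argument")
})

test_that("ties on periodic inputs break toward the smallest absolute lag", {
  rate <- 250
  t <- (0:(30 * rate - 1)) / rate
  per <- signal_ts(sin(2 * pi * 2 * t), rate) # 0.5 s period
  lag <- estimate_event_lag(per, per, 15, max_lag = 2)
  expect_identical(lag, 0) # among all multiples of the period, pick 0
  d <- round(0.5 * rate) # delay by one full period: indistinguishable from 0
  delayed <- signal_ts(c(rep(0, d), per$value[1:(nrow(per) - d)]), rate)
  lag2 <- estimate_event_lag(per, delayed, 15, max_lag = 2)
  expect_identical(lag2, 0)
  # deterministic across repeated calls
  expect_identical(lag2, estimate_event_lag(per, delayed, 15, max_lag = 2))
})

test_that("session offset summaries report signed and absolute means", {
  lr <- session_sync_offset(c(0.1, -0.1))
  expect_equal(lr$session_mean, 0)
  expect_equal(lr$session_abs_mean, 0.1)
  lr2 <- session_sync_offset(0.05)
  expect_equal(lr2$session_mean, 0.05)
  expect_equal(lr2$session_abs_mean, 0.05)
  expect_error(session_sync_offset(numeric(0)),
    class = "multisync_error_argument")
  expect_equal(glance(lr)$n_events, 2)
})

test_that("configured inter-device offsets are recovered from sessions", {
  for (off in c(0, 0.1, 0.334)) {
    cfg <- session_config(duration = 24, offset = off, hrv_sd = 0.03,
      stimulus_times = c(8, 14), channels = c("research_ecg", "monitor_ecg"))
    s <- simulate_session(cfg, seed = 20 + round(off * 100))
    a <- preprocess_research_ecg(s$research$ecg)
    b <- preprocess_monitor_ecg(s$monitor$ecg)
    lags <- vapply(c(8, 14), function(tt) estimate_event_lag(a, b, tt),
      numeric(1))
    expect_true(all(abs(lags - off) <= 1 / 250 + 1e-9))
    lr <- session_sync_offset(lags)
    expect_lt(abs(lr$session_mean - off), 1 / 250 + 1e-9)
  }
})
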