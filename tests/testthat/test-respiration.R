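test_that("cardiac interference is removed without touching respiration", {
  s <- simulate_session(session_config(duration = 40, cardiac_gain = 0.3,
    heart_rate = 150, hrv_sd = 0, channels = c("ip", "monitor_ecg")),
    seed = 5)
  clean <- remove_cardiac_interference(s$monitor$ip, s$monitor$ecg)
  fc <- attr(clean, "cardiac_freq_hz")
  expect_equal(fc, 2.5, tolerance = 0.05) # 150 bpm
  # cardiac line attenuated by at least 20 dB (FFT amplitude ratio)
  amp_at <- function(sig, f) {
    n <- nrow(sig)
    sp <- abs(stats::fft(sig$value - mean(sig$value)))[1:(n %/% 2)]
    fr <- (0:(n %/% 2 - 1)) * sig_rate(sig) / n
    max(sp[abs(fr - f) < 0.15])
  }
  att_db <- 20 * log10(amp_at(s$monitor$ip, fc) / amp_at(clean, fc))
  expect_gt(att_db, 20)
  # with no cardiac coupling the respiratory content is untouched
  ip0 <- simulate_ip(40, seq(1, 38, by = 2), rate = 62.5)
  ecg <- simulate_ecg(40, 150, rate = 250)
  out <- remove_cardiac_interference(ip0, ecg)
  expect_gt(stats::cor(out$value, ip0$value), 0.99)
  # zero in, zero out; no R peaks falls back with a warning
  z <- signal_ts(rep(0, 2500), 62.5)
  expect_warning(zz <- remove_cardiac_interference(z, z), "falling back")
  expect_true(all(abs(zz$value) < 1e-12))
})

test_that("breath detection recovers a clean schedule exactly", {
  breaths <- seq(1, 58, by = 2)
  width <- 0.9
  frac <- 0.5
  ip <- simulate_ip(60, breaths, rate = 62.5, width = width)
  ibi <- detect_breaths(ip, threshold_frac = frac)
  expect_identical(nrow(ibi), length(breaths))
  # detected times sit at the analytic threshold crossing of the
  # raised-cosine excursion, within one sample of the scheduled breaths
  crossing <- width / (2 * pi) * acos(1 - 2 * frac)
  expect_lt(max(abs(ibi$breath_s - (breaths + crossing))), 1 / 62.5 + 1e-9)
  expect_true(all(ibi$ibi_s[-1] > 0))
  expect_identical(sum(is.na(ibi$ibi_s)), 1L)
})

test_that("the adaptive threshold tracks an amplitude halving", {
  breaths <- seq(1, 58, by = 2)
  t <- (0:(60 * 62.5 - 1)) / 62.5
  v <- numeric(length(t))
  for (b in breaths) {
    amp <- if (b < 30) 1 else 0.5 # amplitude halves mid-record
    idx <- which(t >= b & t <= b + 0.9)
    v[idx] <- v[idx] + amp * 0.5 * (1 - cos(2 * pi * (t[idx] - b) / 0.9))
  }
  ibi <- detect_breaths(signal_ts(v, 62.5))
  expect_identical(nrow(ibi), length(breaths)) # zero misses at zero noise
})

test_that("flat or empty records yield an empty breath sequence", {
  expect_identical(nrow(detect_breaths(signal_ts(rep(0, 1000), 62.5))), 0L)
  expect_identical(nrow(detect_breaths(signal_ts(rep(2.5, 1000), 62.5))), 0L)
})

test_that("breath schedules are recovered across a seeded parameter sweep", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      period <- stats::runif(1, 1.2, 3)
      width <- stats::runif(1, 0.5, 0.9 * period)
      breaths <- seq(1, 50 - width, by = period)
      ip <- simulate_ip(50, breaths, rate = 62.5, width = width)
      ibi <- detect_breaths(ip)
      expect_identical(nrow(ibi), length(breaths)) # no misses, no extras
    }
  })
})

test_that("windowed respiratory rate follows the 60/mean-IBI rule", {
  # steady breathing every second: 60 breaths/min in every full window
  rr <- windowed_rr(ibi_sequence(0:60), window = 20, step = 1,
    span = c(0, 60))
  expect_true(all(rr$defined))
  expect_true(all(abs(rr$rr_bpm - 60) < 1e-9))
  # stationary breathing at period T (within the edge-gap bound, so no
  # padding fires) gives exactly 60/T in every window
  for (T in c(1.25, 1.5)) {
    b <- seq(0, 80, by = T)
    rrT <- windowed_rr(ibi_sequence(b), window = 20, step = 1, span = c(0, 80))
    expect_true(all(abs(rrT$rr_bpm - 60 / T) < 1e-9))
  }
})

test_that("edge-gap padding matches the hand-evaluated worked cases", {
  # ten 1 s intervals then a 10 s trailing pause: 60 / (20/11) = 33.0
  rr1 <- windowed_rr(ibi_sequence(0:10), window = 20, step = 20,
    span = c(0, 20))
  expect_equal(rr1$rr_bpm, 33, tolerance = 1e-12)
  expect_equal(rr1$rr_bpm, oracle_window_rr(0:10, 0, 20), tolerance = 1e-12)
  # breaths at 1.0 and 19.5 s: neither edge gap exceeds 1.5 s, rr = 60/18.5
  rr2 <- windowed_rr(ibi_sequence(c(1, 19.5)), window = 20, step = 20,
    span = c(0, 20))
  expect_equal(rr2$rr_bpm, 60 / 18.5, tolerance = 1e-12)
  expect_equal(rr2$rr_bpm, oracle_window_rr(c(1, 19.5), 0, 20),
    tolerance = 1e-12)
})

test_that("padding a pause-sized edge gap lowers the windowed rate", {
  # padding moves the rate toward 60/gap, so it lowers the rate exactly when
  # the padded gap is longer than the mean inside interval — the breathing
  # pause the rule exists for
  withr::with_seed(21, {
    n_pause_cases <- 0
    for (rep in 1:40) {
      breaths <- sort(stats::runif(sample(3:10, 1), 0, 20))
      got <- windowed_rr(ibi_sequence(breaths), window = 20, step = 20,
        span = c(0, 20))
      expect_equal(got$rr_bpm, oracle_window_rr(breaths, 0, 20),
        tolerance = 1e-12)
      inside_mean <- mean(diff(breaths))
      gaps <- c(breaths[1], 20 - breaths[length(breaths)])
      added <- gaps[gaps > 1.5]
      if (length(added) && all(added >= inside_mean)) {
        n_pause_cases <- n_pause_cases + 1
        expect_lte(got$rr_bpm, 60 / inside_mean + 1e-12)
      }
    }
    expect_gt(n_pause_cases, 0) # the sweep actually exercised the rule
  })
})

test_that("windows without breaths are flagged undefined, not zero", {
  rr <- windowed_rr(ibi_sequence(c(30, 31, 32, 33)), window = 20, step = 20,
    span = c(0, 60))
  expect_identical(rr$defined, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(rr$rr_bpm[!rr$defined])))
  expect_error(windowed_rr(ibi_sequence(1:5), window = -1),
    class = "multisync_error_argument")
})
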