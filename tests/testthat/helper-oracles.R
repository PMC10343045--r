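# Independent oracles used to cross-check the package's own algorithms.

# lag oracle via stats::ccf (its acf[k] is cor(x[t+k], y[t]); the covariance
# argmax over k of sum a[t] b[t+k] is then the ccf(b, a) peak)
oracle_lag_samples <- function(a, b, max_lag_samples) {
  cc <- stats::ccf(b, a, lag.max = max_lag_samples, plot = FALSE,
    demean = TRUE)
  lags <- drop(cc$lag)
  vals <- drop(cc$acf)
  cand <- which(vals >= max(vals) - 1e-12)
  cand <- cand[order(abs(lags[cand]), lags[cand])][1]
  lags[cand]
}

# exhaustive local-maximum scan used as the R-peak oracle
oracle_peaks <- function(v, min_height) {
  out <- integer(0)
  for (i in 2:(length(v) - 1)) {
    if (v[i] > v[i - 1] && v[i] >= v[i + 1] && v[i] > min_height) {
      out <- c(out, i)
    }
  }
  out
}

# direct evaluation of the windowed respiratory-rate rule for one window
oracle_window_rr <- function(breaths, win_start, win_end, edge_gap = 1.5) {
  inside <- breaths[breaths >= win_start & breaths <= win_end]
  if (length(inside) == 0) return(NA_real_)
  ibis <- diff(inside)
  if (inside[1] - win_start > edge_gap) ibis <- c(inside[1] - win_start, ibis)
  if (win_end - inside[length(inside)] > edge_gap) {
    ibis <- c(ibis, win_end - inside[length(inside)])
  }
  if (length(ibis) == 0) return(NA_real_)
  60 / mean(ibis)
}

# build an epoch signal containing the template shifted by `shift` seconds
shifted_template_epoch <- function(template, shift, pre = 0.5, post = 1.2,
                                   rate = sig_rate(template)) {
  tt <- seq(-pre, post, by = 1 / rate)
  v <- stats::approx(template$time + shift, template$value, xout = tt,
    yleft = 0, yright = 0)$y
  signal_ts(v, rate = rate, start = -pre)
}

# pull the raw +/- half-window sample vector around a center time
extract_epochs_for_test <- function(sig, center, half = 5) {
  rate <- sig_rate(sig)
  i0 <- round((center - sig_start(sig)) * rate)
  k <- seq.int(-round(half * rate), round(half * rate))
  sig$value[i0 + k + 1]
}

# peak amplitude of a long filtered sinusoid away from the record edges
filter_gain <- function(filter_fun, freq, rate, dur = 20) {
  t <- (0:(dur * rate - 1)) / rate
  out <- filter_fun(signal_ts(sin(2 * pi * freq * t), rate))
  n <- length(t)
  max(abs(out$value[(n %/% 4):(3 * n %/% 4)]))
}
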