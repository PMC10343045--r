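# Zero-phase IIR filtering helpers (Butterworth designs via the signal
# package, applied forward-backward with filtfilt so event timing is never
# shifted by filter group delay). Band-passes are applied as a
# high-pass/low-pass cascade, which stays numerically stable at the very
# small normalised corner frequencies that arise at 2000 Hz (e.g. 0.5 Hz).

# forward-backward filtering with odd-reflection padding at both ends to
# suppress the edge transients signal::filtfilt would otherwise leave
filtfilt_padded <- function(bf, v, pad) {
  n <- length(v)
  pad <- min(n - 1L, pad)
  if (pad < 1L) return(as.numeric(signal::filtfilt(bf, v)))
  head_pad <- 2 * v[1] - v[(pad + 1):2]
  tail_pad <- 2 * v[n] - v[(n - 1):(n - pad)]
  out <- as.numeric(signal::filtfilt(bf, c(head_pad, v, tail_pad)))
  out[(pad + 1):(pad + n)]
}

lowpass_zero_phase <- function(v, rate, cutoff, order = 4) {
  w <- cutoff / (rate / 2)
  if (w >= 1) ms_abort("low-pass cutoff at or above Nyquist", "argument")
  bf <- signal::butter(order, w, type = "low")
  filtfilt_padded(bf, v, round(3 * rate / cutoff))
}

# high-pass as baseline subtraction (x minus its low-passed trend), which is
# numerically robust at the very small normalised corners used on 2000 Hz
# records (e.g. 0.5 Hz) where a direct high-pass Butterworth is fragile
highpass_zero_phase <- function(v, rate, cutoff, order = 2) {
  v - lowpass_zero_phase(v, rate, cutoff, order)
}

bandpass_zero_phase <- function(v, rate, band, order_hp = 2, order_lp = 4) {
  stopifnot(length(band) == 2, band[1] < band[2])
  lowpass_zero_phase(
    highpass_zero_phase(v, rate, band[1], order_hp),
    rate, band[2], order_lp
  )
}

notch_zero_phase <- function(v, rate, freq, half_width = 2, order = 2) {
  w <- c(freq - half_width, freq + half_width) / (rate / 2)
  if (w[2] >= 1) ms_abort("notch frequency at or above Nyquist", "argument")
  bf <- signal::butter(order, w, type = "stop")
  filtfilt_padded(bf, v, round(3 * rate / half_width))
}

# integer-factor zero-phase decimation: band-limit, then keep every k-th
# sample; used when the source rate is an integer multiple of the target
decimate_zero_phase <- function(v, rate, target_rate) {
  k <- rate / target_rate
  if (abs(k - round(k)) < 1e-9) {
    k <- round(k)
    if (k > 1) v <- lowpass_zero_phase(v, rate, 0.4 * target_rate, order = 6)
    v[seq(1, length(v), by = k)]
  } else {
    as.numeric(signal::resample(v, round(target_rate * 1e6), round(rate * 1e6)))
  }
}
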