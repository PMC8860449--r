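# Shared fixtures, all built in code at test time.

FS <- 200

# Gaussian noise confined to [lo, hi] Hz, scaled to a target RMS.
band_noise <- function(n, lo, hi, fs = FS, rms = 25) {
  w <- rnorm(n)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) * fs / n
  sc <- as.numeric(f >= lo & f <= hi)
  x <- Re(fft(fft(w) * sc, inverse = TRUE)) / n
  x * rms / sqrt(mean(x^2))
}

# One SWD embedded in 1/f^2 background: event at `onset` s, flanked by
# background, with a 10 s pre-event baseline available.
make_event_segment <- function(f0, dur, snr = 10, onset = 12, flank = 1,
                               fs = FS, bg_rms = 25, n_harmonics = 4,
                               decay = 0.6) {
  n <- round((onset + dur + flank + 11) * fs)
  x <- swdquant:::pink_noise(n, alpha = 2, fs = fs, rms_target = bg_rms)
  w <- swd_waveform(f0, dur, n_harmonics, decay, fs,
                    amplitude = snr * bg_rms, ramp_s = 0.2)
  i0 <- round(onset * fs) + 1
  x[i0:(i0 + length(w) - 1)] <- x[i0:(i0 + length(w) - 1)] + w
  list(x = x, fs = fs, onset = onset, offset = onset + dur, f0 = f0)
}

# Small two-epoch config for count statistics (15 min pre / 15 min post).
contrast_config <- function(seed, pre_rate = 0.89, post_rate = 1.73) {
  synth_config(
    epochs = data.frame(condition = c("normoxia", "hypoxia"),
                        duration_s = c(900, 900)),
    t_zero = 900,
    swd = list(rate_per_bin = c(normoxia = pre_rate, hypoxia = post_rate)),
    seed = seed)
}
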