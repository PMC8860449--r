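test_that("rms_baseline matches closed forms and a brute-force oracle", {
  fs <- FS
  # constant signal: mean-subtracted RMS is 0
  expect_equal(rms_baseline(rep(3.7, 400), fs, 2, baseline_window = 2,
                            detrend_s = 0), 0)
  # sinusoid of amplitude A over whole cycles: A / sqrt(2)
  t <- (0:(10 * fs - 1)) / fs
  x <- 5 * sin(2 * pi * 5 * t)
  expect_equal(rms_baseline(x, fs, 10, baseline_window = 10,
                            detrend_s = 0), 5 / sqrt(2), tolerance = 1e-6)
  # arbitrary window vs direct loop
  set.seed(8)
  y <- rnorm(2000)
  got <- rms_baseline(y, fs, 10, baseline_window = 10, detrend_s = 0)
  m <- sum(y) / 2000
  acc <- 0
  for (v in y) acc <- acc + (v - m)^2
  expect_equal(got, sqrt(acc / 2000), tolerance = 1e-12)
  # window before recording start
  expect_error(rms_baseline(y, fs, 1, baseline_window = 10,
                            on_short = "reject"), "before the recording")
})

test_that("refine_bounds recovers injected bounds and rejects noise", {
  set.seed(31)
  seg <- make_event_segment(f0 = 6.5, dur = 5)
  rb <- refine_bounds(seg$x, seg$fs, seg$onset - 1, seg$offset + 1)
  expect_false(rb$rejected)
  expect_lt(abs(rb$t_onset - seg$onset), 1 / seg$f0)
  expect_lt(abs(rb$t_offset - seg$offset), 1 / seg$f0)
  expect_equal(rb$threshold, 2.5 * rb$rms_baseline)

  # multiplier -> infinity rejects any finite signal
  rb_inf <- refine_bounds(seg$x, seg$fs, seg$onset - 1, seg$offset + 1,
                          multiplier = Inf)
  expect_true(rb_inf$rejected)
})

test_that("pure background windows are almost always rejected", {
  set.seed(32)
  rejected <- replicate(100, {
    x <- swdquant:::pink_noise(16 * FS, alpha = 2, fs = FS,
                               rms_target = 25)
    refine_bounds(x, FS, 12, 15)$rejected
  })
  expect_gte(mean(rejected), 0.9)
})

test_that("refined duration is monotone non-increasing in the multiplier", {
  set.seed(33)
  for (i in 1:20) {
    seg <- make_event_segment(f0 = runif(1, 5, 8), dur = runif(1, 2, 8))
    base <- rms_baseline(seg$x, seg$fs, seg$onset - 1)
    last_dur <- Inf
    for (m in c(0, 1, 2.5, 5, 10)) {
      rb <- refine_bounds(seg$x, seg$fs, seg$onset - 1, seg$offset + 1,
                          multiplier = m, baseline_rms = base)
      d <- if (rb$rejected) 0 else rb$t_offset - rb$t_onset
      expect_lte(d, last_dur + 1e-12)
      last_dur <- d
    }
  }
})

test_that("at multiplier 0 bounds are the first/last local maxima", {
  set.seed(34)
  x <- rnorm(600)
  rb <- refine_bounds(x, FS, 0.5, 2.5, multiplier = 0, baseline_rms = 1,
                      detrend_s = 0)
  i0 <- floor(0.5 * FS) + 1
  i1 <- floor(2.5 * FS)
  y <- abs(x[i0:i1] - mean(x[i0:i1]))
  pk <- which(diff(sign(diff(y))) < 0) + 1
  expect_equal(rb$t_onset, (i0 + pk[1] - 2) / FS)
  expect_equal(rb$t_offset, (i0 + pk[length(pk)] - 2) / FS)
})

test_that("joint rescaling of the signal leaves refined bounds unchanged", {
  set.seed(35)
  seg <- make_event_segment(f0 = 7, dur = 4)
  rb1 <- refine_bounds(seg$x, seg$fs, seg$onset - 1, seg$offset + 1)
  rb2 <- refine_bounds(seg$x * 13.7, seg$fs, seg$onset - 1, seg$offset + 1)
  expect_equal(rb1$t_onset, rb2$t_onset)
  expect_equal(rb1$t_offset, rb2$t_offset)
  expect_equal(rb2$rms_baseline, 13.7 * rb1$rms_baseline)
})

test_that("event_duration is the difference of the refined bounds", {
  expect_equal(event_duration(10.0, 15.3), 5.3)
  expect_equal(event_duration(3, 3), 0)
  expect_error(event_duration(5, 4), "t_offset")
})

test_that("event_frequency is exact for on-grid cosines and breaks ties low", {
  fs <- FS
  t <- (0:(5 * fs - 1)) / fs
  x <- cos(2 * pi * 6 * t)
  fr <- event_frequency(x, fs, 0, 5)
  expect_equal(fr$dominant_freq, 6.0)
  expect_false(fr$low_confidence)
  # equal-power 5 + 9 Hz mixture: documented tie-break to the lower
  t <- (0:(10 * fs - 1)) / fs
  x2 <- cos(2 * pi * 5 * t) + cos(2 * pi * 9 * t)
  expect_equal(event_frequency(x2, fs, 0, 10)$dominant_freq, 5.0)
  # sub-cycle segment is flagged
  expect_true(event_frequency(x, fs, 0, 0.2)$low_confidence)
})

test_that("noiseless harmonic combs are recovered exactly on a 0.5 Hz grid", {
  set.seed(36)
  for (f0 in seq(5, 8, by = 0.5)) {
    w <- swd_waveform(f0, 4, 4, 0.6, FS, amplitude = 1)
    fr <- event_frequency(w, FS, 0, 4)
    expect_equal(fr$dominant_freq, f0, tolerance = 1e-9,
                 label = paste("f0 =", f0))
  }
})

test_that("min_duration_filter is inclusive at 2 s and idempotent", {
  ev <- data.frame(duration = c(1.9, 2.0, 5.3))
  expect_equal(min_duration_filter(ev)$duration, c(2.0, 5.3))
  expect_equal(nrow(min_duration_filter(ev[0, , drop = FALSE])), 0)
  expect_equal(min_duration_filter(ev, min_s = 0)$duration, ev$duration)
  once <- min_duration_filter(ev)
  expect_identical(min_duration_filter(once), once)
})

test_that("atonia_check compares event to baseline EMG RMS", {
  set.seed(37)
  fs <- FS
  emg <- rnorm(30 * fs, 0, 50)
  ev_idx <- (15 * fs + 1):(20 * fs)
  emg_at <- emg
  emg_at[ev_idx] <- emg_at[ev_idx] * 0.2
  expect_true(atonia_check(emg_at, fs, 15, 20))
  expect_false(atonia_check(emg, fs, 15, 20))
  expect_warning(ok <- atonia_check(NULL, fs, 15, 20), "skipped")
  expect_true(ok)
  expect_error(atonia_check(NULL, fs, 15, 20, strict = TRUE), "EMG")
})

test_that("atonia at drop_fraction 1 accepts any attenuated event", {
  set.seed(38)
  fs <- FS
  for (i in 1:100) {
    emg <- rnorm(30 * fs, 0, 50)
    af <- runif(1, 0, 0.8)
    ev_idx <- (15 * fs + 1):(20 * fs)
    emg[ev_idx] <- emg[ev_idx] * af
    expect_true(atonia_check(emg, fs, 15, 20, drop_fraction = 1.0))
  }
})

test_that("spectrogram shows the expected ridge and matches an oracle", {
  fs <- FS
  t <- (0:(8 * fs - 1)) / fs
  x <- cos(2 * pi * 7 * t)
  sp <- spectrogram(x, fs)
  ridge <- sp$freqs[apply(sp$power, 1, which.max)]
  expect_true(all(abs(ridge - 7) <= 0.25))
  expect_true(all(sp$power >= 0))
  expect_lte(max(sp$freqs), fs / 2)

  sp0 <- spectrogram(numeric(3 * fs), fs)
  expect_true(all(sp0$power == 0))

  # column-wise equality with an independently computed windowed
  # periodogram (Hann window, half-overlap, 4x zero padding)
  set.seed(39)
  y <- rnorm(1000)
  spy <- spectrogram(y, fs)
  wlen <- fs
  nfft <- 4 * wlen
  han <- 0.5 - 0.5 * cos(2 * pi * seq(0, wlen - 1) / (wlen - 1))
  ym <- y - mean(y)
  for (j in seq_along(spy$times)) {
    start <- 1 + (j - 1) * (wlen %/% 2)
    seg <- ym[start:(start + wlen - 1)] * han
    ora <- Mod(fft(c(seg, numeric(nfft - wlen))))^2
    expect_equal(spy$power[j, ], ora[seq_along(spy$freqs)],
                 tolerance = 1e-8)
  }
  expect_error(spectrogram(rnorm(10), fs), "longer")
})

test_that("harmonic score separates combs from tones and slow waves", {
  fs <- FS
  set.seed(40)
  # constructed SWD: harmonic
  seg <- make_event_segment(f0 = 6, dur = 5)
  sp <- spectrogram(seg$x, fs)
  h <- harmonic_score(sp, seg$onset, seg$offset)
  expect_true(h$is_harmonic)
  expect_equal(h$f0, 6, tolerance = 0.3)
  # pure sinusoid: no harmonic energy
  t <- (0:(10 * fs - 1)) / fs
  x <- 200 * cos(2 * pi * 6 * t) +
    swdquant:::pink_noise(10 * fs, 2, fs, 25)
  h2 <- harmonic_score(spectrogram(x, fs), 2, 8)
  expect_false(h2$is_harmonic)
  # slow-wave surrogates: majority non-harmonic
  hits <- replicate(50, {
    y <- swdquant:::pink_noise(10 * fs, 2, fs, 25) +
      band_noise(10 * fs, 1, 4, fs, 125)
    !harmonic_score(spectrogram(y, fs), 2, 8)$is_harmonic
  })
  expect_gte(mean(hits), 0.9)
})

test_that("process_events composes refine/filter/characterize correctly", {
  cfg <- synth_config(epochs = data.frame(condition = "hypoxia",
                                          duration_s = 1200), seed = 12)
  sess <- generate_session(cfg)
  tr <- sess$truth$events
  stopifnot(nrow(tr) >= 2)  # deterministic: this seed yields several events
  set.seed(13)
  co <- coarse_events(
    pmax(0.1, tr$t_start - 1 + rnorm(nrow(tr), 0, 0.25)),
    pmin(sess$recording$duration, tr$t_end + 1 + rnorm(nrow(tr), 0, 0.25)))
  ev <- process_events(sess$recording, co)
  expect_s3_class(ev, "swd_events")
  truth_ok <- tr[tr$t_end - tr$t_start >= 2, ]
  # every accepted event overlaps a true event by at least half
  for (i in seq_len(nrow(ev))) {
    ov <- pmin(ev$t_offset[i], tr$t_end) - pmax(ev$t_onset[i], tr$t_start)
    expect_gte(max(ov / (tr$t_end - tr$t_start)), 0.5)
  }
  expect_gte(nrow(ev), floor(0.9 * nrow(truth_ok)))
  expect_true(all(ev$duration >= 2))
  expect_true(all(ev$is_harmonic))
  expect_true(all(ev$atonia_ok))

  # no coarse events -> empty result
  e0 <- process_events(sess$recording, coarse_events())
  expect_equal(nrow(e0), 0)

  # all-short candidates -> empty with logged rejections
  short <- coarse_events(c(100, 300), c(100.8, 300.7))
  es <- process_events(sess$recording, short)
  expect_equal(nrow(es), 0)
  expect_equal(nrow(attr(es, "rejections")), 2)
})
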