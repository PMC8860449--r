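test_that("swd_waveform has its dominant component at f0", {
  set.seed(1)
  w <- swd_waveform(7, 4, 4, 0.6, FS, amplitude = 1)
  p <- Mod(fft(c(w, numeric(4000 - length(w)))))^2
  fr <- (seq_along(p) - 1) * FS / 4000
  sel <- fr >= 4 & fr <= 12
  expect_lt(abs(fr[sel][which.max(p[sel])] - 7), 0.3)
  expect_error(swd_waveform(30, 2, 4, 0.6, FS), "Nyquist")
})

test_that("single-harmonic waveform has a single spectral peak", {
  set.seed(2)
  w <- swd_waveform(6, 5, 1, 0.6, FS, amplitude = 1)
  p <- Mod(fft(c(w, numeric(4000 - length(w)))))^2
  fr <- (seq_along(p) - 1) * FS / 4000
  half <- fr <= 100
  p6 <- max(p[half][fr[half] > 5 & fr[half] < 7])
  p12 <- max(p[half][fr[half] > 11 & fr[half] < 13])
  expect_gt(p6 / p12, 1e3)
})

test_that("harmonic power follows the geometric decay", {
  # decay 0.5 => second-harmonic power ~ 0.25 x fundamental power
  set.seed(3)
  w <- swd_waveform(7, 8, 2, 0.5, FS, amplitude = 1)
  p <- Mod(fft(c(w, numeric(8000 - length(w)))))^2
  fr <- (seq_along(p) - 1) * FS / 8000
  p7 <- max(p[fr > 6 & fr < 8])
  p14 <- max(p[fr > 13 & fr < 15])
  expect_equal(p14 / p7, 0.25, tolerance = 0.10)
})

test_that("laser schedule: 40 pulses per train, gap respected, truncation", {
  cfg <- synth_config(laser = list(total_min = 4 / 60))
  sch <- laser_schedule(cfg$laser)
  expect_equal(nrow(sch), 40)
  expect_true(all(sch$t_on < 2))
  expect_true(all(diff(sch$t_on) - 0.05 < 1e-9))
  expect_true(all(sch$t_off - sch$t_on - 0.010 < 1e-9))

  expect_equal(nrow(laser_schedule(synth_config(
    laser = list(total_min = 0))$laser)), 0)

  sch60 <- laser_schedule(synth_config(laser = list(total_min = 1))$laser)
  expect_equal(nrow(sch60), 15 * 40)

  expect_error(laser_schedule(synth_config(
    laser = list(pulse_width_s = 0.06))$laser), "period")
})

test_that("laser schedule matches closed-form pulse count", {
  closed_form <- function(total_s, on = 2, off = 2, rate = 20) {
    cyc <- on + off
    nf <- floor(total_s / cyc)
    rem <- total_s - nf * cyc
    nf * on * rate + ceiling(min(rem, on) * rate - 1e-9)
  }
  for (total_s in c(0.5, 1.234, 4, 7.3, 60, 61.02, 123.456)) {
    sch <- laser_schedule(synth_config(
      laser = list(total_min = total_s / 60))$laser)
    expect_equal(nrow(sch), closed_form(total_s), label = paste(total_s))
  }
})

test_that("identical seed gives a bitwise-identical session", {
  cfg <- synth_config(epochs = data.frame(condition = "normoxia",
                                          duration_s = 120), seed = 7)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$recording$channels, s2$recording$channels)
  expect_identical(s1$truth$events, s2$truth$events)
})

test_that("zero rate gives pure background with no events", {
  cfg <- synth_config(epochs = data.frame(condition = "normoxia",
                                          duration_s = 120),
                      swd = list(rate_per_bin = c(normoxia = 0)), seed = 3)
  s <- generate_session(cfg)
  expect_equal(nrow(s$truth$events), 0)
  # background RMS at the configured level
  expect_equal(sqrt(mean(s$recording$channels$ecog^2)), 25,
               tolerance = 0.01)
})

test_that("injected events are non-overlapping and inside the session", {
  set.seed(99)
  for (i in 1:150) {
    cfg <- synth_config(
      epochs = data.frame(condition = c("normoxia", "hypoxia"),
                          duration_s = round(runif(2, 300, 1200))),
      swd = list(rate_per_bin = c(normoxia = runif(1, 0, 3),
                                  hypoxia = runif(1, 0, 3))),
      seed = sample.int(2^31 - 2, 1))
    ev <- generate_events(cfg)
    if (nrow(ev) > 1) {
      expect_true(all(ev$t_start[-1] >= ev$t_end[-nrow(ev)]))
    }
    expect_true(all(ev$t_start >= 0))
    expect_true(all(ev$t_end <= sum(cfg$epochs$duration_s)))
    expect_true(all(ev$f0 >= 5 & ev$f0 <= 8))
  }
})

test_that("generated respiration matches its schedule by zero crossings", {
  cfg <- synth_config(
    epochs = data.frame(condition = c("normoxia", "hypoxia"),
                        duration_s = c(120, 120)),
    resp = list(rate_jitter_sd = 0, jitter_block_s = 60), seed = 5)
  s <- generate_session(cfg)
  x <- s$recording$channels$resp
  tt <- sample_times(s$recording)
  for (i in seq_len(nrow(s$truth$resp_schedule))) {
    seg <- s$truth$resp_schedule[i, ]
    idx <- tt >= seg$t_start & tt < seg$t_end
    zc <- sum(diff(sign(x[idx])) != 0) / 2
    emp <- zc / (seg$t_end - seg$t_start)
    expect_equal(emp, seg$rate_hz, tolerance = 0.02)
  }
})

test_that("background periodogram slope on log-log axes is about -alpha", {
  set.seed(11)
  slopes <- replicate(30, {
    x <- swdquant:::pink_noise(4000, alpha = 2, fs = FS, rms_target = 1)
    p <- Mod(fft(x))^2
    fr <- (seq_along(p) - 1) * FS / 4000
    sel <- fr >= 1 & fr <= 50
    coef(lm(log(p[sel]) ~ log(fr[sel])))[2]
  })
  expect_equal(mean(slopes), -2, tolerance = 0.2)
})

test_that("gas channels relax exponentially to the epoch target", {
  cfg <- synth_config(epochs = data.frame(
    condition = c("normoxia", "hypoxia"), duration_s = c(60, 900)),
    seed = 2)
  s <- generate_session(cfg)
  o2 <- s$recording$channels$gas_o2
  tt <- sample_times(s$recording)
  expect_equal(o2[1], 21, tolerance = 1e-6)
  # one tau (200 s) into hypoxia the excess should have decayed to 1/e
  i_tau <- which.min(abs(tt - (60 + 200)))
  expect_equal(o2[i_tau], 10 + (21 - 10) * exp(-1), tolerance = 0.05)
  expect_equal(o2[length(o2)], 10, tolerance = 0.15)
})

test_that("per-bin event counts track the configured rate", {
  # Monte-Carlo: post-exchange bins at 1.73 events/bin
  set.seed(21)
  post_means <- replicate(150, {
    cfg <- contrast_config(sample.int(2^31 - 2, 1))
    ev <- generate_events(cfg)
    mean(bin_counts(align_events(ev, 900))[4:6])
  })
  se <- sqrt(1.73 / (150 * 3))
  expect_lt(abs(mean(post_means) - 1.73), 2 * se)
})
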