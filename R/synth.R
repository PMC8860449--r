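#' Configuration for the synthetic session generator
#'
#' Defaults encode the study conditions the analysis targets: 200 Hz
#' acquisition, 40 min normoxia followed by 20 min hypoxia with the
#' peristimulus origin at the gas exchange, spike-wave discharge (SWD)
#' rates and breathing rates per condition at the reported group means,
#' 5-8 Hz harmonic-comb SWD morphology, EMG atonia during events,
#' exponential chamber-gas exchange (tau = chamber volume / flow =
#' 5 L / 1.5 L min^-1 = 200 s), and 20 Hz / 10 ms laser pulse trains gated
#' 2 s on / 2 s off.
#'
#' @param fs Sampling rate, Hz.
#' @param epochs Data frame `condition`, `duration_s` defining the session
#'   as consecutive epochs from t = 0.
#' @param t_zero Alignment origin (s); default the end of the first epoch.
#' @param background `noise_exponent` alpha (ECoG background is 1/f^alpha
#'   Gaussian noise) and `amplitude_uV` (RMS).
#' @param swd SWD burst parameters: `rate_per_bin` (expected events per
#'   5-min bin, named by condition), `f0_range` (fundamental, Hz),
#'   `n_harmonics`, `harmonic_decay` (geometric amplitude ratio between
#'   successive harmonics), `duration_mean_s`/`duration_sd_s` (lognormal on
#'   the natural scale), `amplitude_uV` (fundamental amplitude; default SNR
#'   of 10 against the background RMS), `ramp_s` (raised-cosine envelope
#'   ramps).
#' @param emg `tone_uV` (baseline RMS) and `atonia_fraction` (EMG amplitude
#'   multiplier during events).
#' @param resp `rate_by_condition` (Hz), `rate_jitter_sd` (Hz, slow
#'   breath-rate wander), `jitter_block_s` (wander holds constant over
#'   blocks of this length).
#' @param gas `exchange_tau_s` plus per-condition `o2_pct`/`co2_pct`
#'   targets.
#' @param laser Pulse-train parameters `pulse_rate_hz`, `pulse_width_s`,
#'   `train_on_s`, `train_off_s`, `total_min` (0 disables the laser),
#'   `start_s` (default `t_zero`).
#' @param seed Integer master seed; per-channel sub-streams are derived
#'   from it, so one seed reproduces the full session.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(
    fs = 200,
    epochs = data.frame(condition = c("normoxia", "hypoxia"),
                        duration_s = c(2400, 1200)),
    t_zero = NULL,
    background = list(),
    swd = list(),
    emg = list(),
    resp = list(),
    gas = list(),
    laser = list(),
    seed = 1L) {
  merge_block <- function(defaults, user) {
    if (length(user) > 0) defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    fs = fs,
    epochs = epochs,
    t_zero = t_zero,
    bin_s = 300,
    background = merge_block(
      list(noise_exponent = 2, amplitude_uV = 25), background),
    swd = merge_block(
      list(rate_per_bin = c(normoxia = 0.89, hypoxia = 1.73,
                            hypoxia_co2 = 0.84, normoxia_co2 = 0.95),
           f0_range = c(5, 8), n_harmonics = 4, harmonic_decay = 0.6,
           duration_mean_s = 5.5, duration_sd_s = 2,
           amplitude_uV = 250, ramp_s = 0.2), swd),
    emg = merge_block(
      list(tone_uV = 50, atonia_fraction = 0.2), emg),
    resp = merge_block(
      list(rate_by_condition = c(normoxia = 1.03, hypoxia = 1.33,
                                 hypoxia_co2 = 1.88, normoxia_co2 = 1.78),
           rate_jitter_sd = 0.02, jitter_block_s = 10), resp),
    gas = merge_block(
      list(exchange_tau_s = 200,
           o2_pct = c(normoxia = 21, hypoxia = 10, hypoxia_co2 = 10,
                      normoxia_co2 = 21),
           co2_pct = c(normoxia = 0, hypoxia = 0, hypoxia_co2 = 5,
                       normoxia_co2 = 5)), gas),
    laser = merge_block(
      list(pulse_rate_hz = 20, pulse_width_s = 0.010, train_on_s = 2,
           train_off_s = 2, total_min = 0, start_s = NULL), laser),
    seed = as.integer(seed)
  )
  stopifnot(is.data.frame(cfg$epochs),
            all(c("condition", "duration_s") %in% names(cfg$epochs)))
  if (any(cfg$epochs$duration_s <= 0)) {
    stop("every epoch must have positive duration")
  }
  if (cfg$fs <= 0) stop("fs must be positive")
  f_hi <- max(cfg$swd$f0_range) * cfg$swd$n_harmonics
  if (f_hi >= cfg$fs / 2) {
    stop("highest SWD harmonic (", f_hi, " Hz) must be below Nyquist (",
         cfg$fs / 2, " Hz); reduce n_harmonics or f0_range")
  }
  if (any(cfg$swd$rate_per_bin < 0)) stop("rates must be non-negative")
  af <- cfg$emg$atonia_fraction
  if (af < 0 || af > 1) stop("atonia_fraction must be in [0, 1]")
  boundaries <- cumsum(c(0, cfg$epochs$duration_s))
  if (is.null(cfg$t_zero)) {
    cfg$t_zero <- if (nrow(cfg$epochs) > 1) boundaries[2] else 0
  }
  class(cfg) <- "synth_config"
  cfg
}

config_timeline <- function(cfg) {
  b <- cumsum(c(0, cfg$epochs$duration_s))
  protocol_timeline(
    data.frame(t_start = b[-length(b)], t_end = b[-1],
               condition = cfg$epochs$condition),
    t_zero = cfg$t_zero)
}

#' Synthetic spike-wave discharge waveform
#'
#' A harmonic comb: `sum_k a * decay^(k-1) * cos(2 pi k f0 t + phi_k)`,
#' enveloped with raised-cosine onset/offset ramps. This reproduces the
#' spectral signature by which SWDs are told apart from non-REM sleep — a
#' 5-8 Hz fundamental with stacked harmonics in the spectrogram — without
#' asserting any particular spike morphology.
#'
#' @param f0 Fundamental frequency, Hz.
#' @param duration Seconds.
#' @param n_harmonics Number of harmonic components (all below Nyquist).
#' @param harmonic_decay Amplitude ratio between successive harmonics.
#' @param fs Sampling rate, Hz.
#' @param amplitude Fundamental amplitude (uV in session context).
#' @param ramp_s Envelope ramp length, s (clipped to half the duration).
#' @param phases Optional vector of harmonic phases (radians); drawn
#'   uniformly from the current RNG stream when `NULL`.
#' @return Numeric vector of `round(duration * fs)` samples.
#' @export
swd_waveform <- function(f0, duration, n_harmonics = 4, harmonic_decay = 0.6,
                         fs = 200, amplitude = 1, ramp_s = 0.2,
                         phases = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (f0 * n_harmonics >= fs / 2) {
    stop("harmonic ", n_harmonics, " x ", f0, " Hz is at or above Nyquist")
  }
  if (is.null(phases)) phases <- stats::runif(n_harmonics, 0, 2 * pi)
  n <- max(1L, round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (k in seq_len(n_harmonics)) {
    x <- x + amplitude * harmonic_decay^(k - 1) *
      cos(2 * pi * k * f0 * t + phases[k])
  }
  ramp_s <- min(ramp_s, duration / 2)
  nr <- round(ramp_s * fs)
  env <- rep(1, n)
  if (nr > 0) {
    r <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    env[seq_len(nr)] <- r
    env[n + 1 - seq_len(nr)] <- r
  }
  x * env
}

#' Laser pulse-train schedule
#'
#' Pulses at `pulse_rate_hz` (period 50 ms at the default 20 Hz), each
#' `pulse_width_s` long, delivered in `train_on_s` trains separated by
#' `train_off_s` rest (40 pulses per 2 s train at the defaults), repeated
#' for `total_min` minutes and truncated at the total duration.
#'
#' @param laser List of laser parameters (see [synth_config()]); a full
#'   `synth_config` is also accepted.
#' @param start_s Schedule start on the session clock (s), default 0.
#' @return Data frame `t_on`, `t_off` (seconds), one row per pulse.
#' @export
laser_schedule <- function(laser = synth_config()$laser, start_s = 0) {
  if (inherits(laser, "synth_config")) laser <- laser$laser
  period <- 1 / laser$pulse_rate_hz
  if (laser$pulse_width_s >= period) {
    stop("pulse width (", laser$pulse_width_s,
         " s) must be shorter than the pulse period (", period, " s)")
  }
  total_s <- laser$total_min * 60
  if (total_s <= 0) {
    return(data.frame(t_on = numeric(), t_off = numeric()))
  }
  cycle <- laser$train_on_s + laser$train_off_s
  t_on <- numeric(0)
  train_start <- 0
  while (train_start < total_s) {
    p <- seq(0, laser$train_on_s - period / 2, by = period)
    p <- train_start + p
    t_on <- c(t_on, p[p < total_s])
    train_start <- train_start + cycle
  }
  data.frame(t_on = start_s + t_on,
             t_off = start_s + pmin(t_on + laser$pulse_width_s, total_s))
}

# Gaussian 1/f^alpha noise via spectral shaping, scaled to rms_target.
# A first-order high-pass corner (default 0.1 Hz) reproduces the
# acquisition band-pass of the recordings being emulated.
pink_noise <- function(n, alpha = 2, fs = 200, rms_target = 1,
                       f_hp = 0.1) {
  w <- stats::rnorm(n)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) * fs / n            # |frequency| of each FFT bin
  scale <- numeric(n)
  pos <- f > 0
  scale[pos] <- f[pos]^(-alpha / 2)
  if (f_hp > 0) {
    scale[pos] <- scale[pos] * f[pos] / sqrt(f[pos]^2 + f_hp^2)
  }
  if (alpha == 0 && f_hp <= 0) return(w * rms_target / stats::sd(w))
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  x * rms_target / sqrt(mean(x^2))
}

# Piecewise-homogeneous Poisson placement of SWD events: per 5-min bin
# (aligned to each epoch's start) the event count is Poisson with the
# condition's rate; onsets are uniform within the bin; durations lognormal;
# f0 uniform on f0_range. Overlapping placements are redrawn within the
# same bin (cap 100 tries, then the event is skipped). Uses the current
# RNG stream.
place_events <- function(cfg) {
  tl <- config_timeline(cfg)
  ep <- tl$epochs
  sw <- cfg$swd
  sdlog <- sqrt(log(1 + (sw$duration_sd_s / sw$duration_mean_s)^2))
  meanlog <- log(sw$duration_mean_s) - sdlog^2 / 2
  session_end <- max(ep$t_end)
  t_start <- t_end <- f0 <- numeric(0)
  for (i in seq_len(nrow(ep))) {
    rate <- sw$rate_per_bin[[ep$condition[i]]]
    if (is.null(rate) || is.na(rate)) rate <- 0
    bin_lo <- seq(ep$t_start[i], ep$t_end[i] - 1e-9, by = cfg$bin_s)
    bin_lo <- bin_lo[ep$t_end[i] - bin_lo > 1e-6]
    for (lo in bin_lo) {
      hi <- min(lo + cfg$bin_s, ep$t_end[i])
      lambda <- rate * (hi - lo) / cfg$bin_s
      n_ev <- stats::rpois(1, lambda)
      for (j in seq_len(n_ev)) {
        dur <- stats::rlnorm(1, meanlog, sdlog)
        ok <- FALSE
        for (try in seq_len(100)) {
          on <- stats::runif(1, lo, hi)
          off <- on + dur
          if (off > session_end) next
          if (all(on >= t_end | off <= t_start)) { ok <- TRUE; break }
        }
        if (ok) {
          t_start <- c(t_start, on)
          t_end <- c(t_end, off)
          f0 <- c(f0, stats::runif(1, sw$f0_range[1], sw$f0_range[2]))
        }
      }
    }
  }
  o <- order(t_start)
  data.frame(t_start = t_start[o], t_end = t_end[o], f0 = f0[o])
}

#' Generate ground-truth SWD event times only
#'
#' Runs the generator's event-placement stage without synthesizing signals
#' — convenient for count-statistics studies (peristimulus histograms,
#' paired contrasts) where only event times matter.
#'
#' @param cfg A [synth_config()].
#' @return Data frame `t_start`, `t_end`, `f0`.
#' @export
generate_events <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  place_events(cfg)
}

# Breathing-rate schedule: condition mean plus slow wander held constant
# over jitter_block_s blocks; rates floored at 0.2 Hz. Uses current RNG.
make_resp_schedule <- function(cfg) {
  tl <- config_timeline(cfg)
  ep <- tl$epochs
  t_start <- t_end <- rate <- numeric(0)
  for (i in seq_len(nrow(ep))) {
    mu <- cfg$resp$rate_by_condition[[ep$condition[i]]]
    if (is.null(mu) || is.na(mu)) mu <- 1
    lo <- seq(ep$t_start[i], ep$t_end[i] - 1e-9,
              by = cfg$resp$jitter_block_s)
    hi <- pmin(lo + cfg$resp$jitter_block_s, ep$t_end[i])
    keep <- hi - lo > 1e-6
    lo <- lo[keep]; hi <- hi[keep]
    r <- pmax(0.2, mu + stats::rnorm(length(lo), 0, cfg$resp$rate_jitter_sd))
    t_start <- c(t_start, lo); t_end <- c(t_end, hi); rate <- c(rate, r)
  }
  data.frame(t_start = t_start, t_end = t_end, rate_hz = rate)
}

#' Generate a synthetic recording session with ground truth
#'
#' Produces a full multi-channel [recording()] plus the ground truth needed
#' to verify every analysis stage: ECoG is 1/f^alpha Gaussian background
#' with harmonic SWD bursts injected at condition-dependent Poisson rates;
#' EMG is broadband noise attenuated to `atonia_fraction` during events;
#' respiration is a phase-continuous sinusoid following the breathing-rate
#' schedule; chamber O2/CO2 relax exponentially to each epoch's target; the
#' laser channel follows the pulse-train schedule. The same seed always
#' yields a bitwise-identical session.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `recording` (a [recording()]) and `truth`
#'   (list: `events` data frame with `t_start`, `t_end`, `f0`;
#'   `resp_schedule` data frame; `timeline`, a [protocol_timeline()]).
#' @export
generate_session <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  tl <- config_timeline(cfg)
  fs <- cfg$fs
  n <- round(sum(cfg$epochs$duration_s) * fs)
  tt <- (seq_len(n) - 1) / fs

  set.seed(cfg$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 5)

  # -- events + ECoG ---------------------------------------------------
  set.seed(sub[1])
  events <- place_events(cfg)
  set.seed(sub[2])
  ecog <- pink_noise(n, cfg$background$noise_exponent, fs,
                     cfg$background$amplitude_uV)
  for (i in seq_len(nrow(events))) {
    w <- swd_waveform(events$f0[i], events$t_end[i] - events$t_start[i],
                      cfg$swd$n_harmonics, cfg$swd$harmonic_decay, fs,
                      amplitude = cfg$swd$amplitude_uV,
                      ramp_s = cfg$swd$ramp_s)
    i0 <- round(events$t_start[i] * fs) + 1
    idx <- i0:(i0 + length(w) - 1)
    keep <- idx >= 1 & idx <= n
    ecog[idx[keep]] <- ecog[idx[keep]] + w[keep]
  }

  # -- EMG with atonia during events ----------------------------------
  set.seed(sub[3])
  emg <- stats::rnorm(n, 0, cfg$emg$tone_uV)
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      idx <- which(tt >= events$t_start[i] & tt < events$t_end[i])
      emg[idx] <- emg[idx] * cfg$emg$atonia_fraction
    }
  }

  # -- respiration -----------------------------------------------------
  set.seed(sub[4])
  sched <- make_resp_schedule(cfg)
  rate_t <- rep(sched$rate_hz[1], n)
  for (i in seq_len(nrow(sched))) {
    rate_t[tt >= sched$t_start[i] & tt < sched$t_end[i]] <- sched$rate_hz[i]
  }
  resp <- sin(2 * pi * cumsum(rate_t) / fs)

  # -- chamber gas (deterministic exponential relaxation) -------------
  o2 <- numeric(n); co2 <- numeric(n)
  tau <- cfg$gas$exchange_tau_s
  o2_prev <- cfg$gas$o2_pct[[tl$epochs$condition[1]]]
  co2_prev <- cfg$gas$co2_pct[[tl$epochs$condition[1]]]
  for (i in seq_len(nrow(tl$epochs))) {
    cond <- tl$epochs$condition[i]
    idx <- which(tt >= tl$epochs$t_start[i] & tt < tl$epochs$t_end[i])
    dt <- tt[idx] - tl$epochs$t_start[i]
    o2_tgt <- cfg$gas$o2_pct[[cond]]; co2_tgt <- cfg$gas$co2_pct[[cond]]
    o2[idx] <- o2_tgt + (o2_prev - o2_tgt) * exp(-dt / tau)
    co2[idx] <- co2_tgt + (co2_prev - co2_tgt) * exp(-dt / tau)
    o2_prev <- o2[idx[length(idx)]]; co2_prev <- co2[idx[length(idx)]]
  }

  # -- laser TTL -------------------------------------------------------
  laser <- numeric(n)
  if (cfg$laser$total_min > 0) {
    start_s <- if (is.null(cfg$laser$start_s)) cfg$t_zero else
      cfg$laser$start_s
    pulses <- laser_schedule(cfg$laser, start_s = start_s)
    for (i in seq_len(nrow(pulses))) {
      idx <- which(tt >= pulses$t_on[i] & tt < pulses$t_off[i])
      laser[idx] <- 1
    }
  }

  rec <- recording(list(ecog = ecog, emg = emg, resp = resp,
                        gas_o2 = o2, gas_co2 = co2, laser = laser),
                   fs = fs)
  list(recording = rec,
       truth = list(events = events, resp_schedule = sched, timeline = tl))
}
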