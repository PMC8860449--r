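#' Windowed-FFT respiratory rate
#'
#' The plethysmography flow trace is partitioned into consecutive
#' non-overlapping windows (10 s by default); each window is
#' mean-subtracted and Fourier-transformed, and the window's respiratory
#' rate is the frequency of maximal power density within the search band.
#' A trailing partial window is dropped; an all-zero window yields `NA`
#' and is skipped by the smoother.
#'
#' @param x Respiration signal.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, s (10 s gives a 0.1 Hz native grid).
#' @param band Search band, Hz; 0.5-4 Hz brackets rat breathing (roughly
#'   0.8-2 Hz across conditions) while excluding DC drift and movement
#'   artifact.
#' @param pad_factor Zero-padding factor for sub-resolution argmax
#'   refinement (ties resolve to the lower frequency); set to 1 for strict
#'   native-resolution bins.
#' @param start_time Session time of the first sample, s.
#' @return Data frame of class `resp_rate_series` with columns
#'   `window_center_s`, `raw_hz`, `smoothed_hz` (`NA` until
#'   [smooth_rate()]), and attributes `window_s`, `band`.
#' @export
respiratory_rate <- function(x, fs, window_s = 10, band = c(0.5, 4),
                             pad_factor = 4, start_time = 0) {
  wlen <- round(window_s * fs)
  n_win <- length(x) %/% wlen
  if (n_win < 1) {
    stop("signal (", length(x) / fs, " s) is shorter than one ",
         window_s, " s window; no rate can be estimated")
  }
  if (band[1] <= 0 || band[2] >= fs / 2) stop("band must be within (0, fs/2)")
  nfft <- wlen * pad_factor
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  raw <- vapply(seq_len(n_win), function(i) {
    seg <- x[((i - 1) * wlen + 1):(i * wlen)]
    seg <- seg - mean(seg)
    if (all(seg == 0)) return(NA_real_)
    p <- Mod(stats::fft(c(seg, numeric(nfft - wlen))))^2
    freqs[in_band[which.max(p[in_band])]]
  }, numeric(1))
  out <- data.frame(
    window_center_s = start_time + (seq_len(n_win) - 0.5) * window_s,
    raw_hz = raw, smoothed_hz = NA_real_)
  attr(out, "window_s") <- window_s
  attr(out, "band") <- band
  class(out) <- c("resp_rate_series", "data.frame")
  out
}

#' Moving-average smoothing of the rate trace
#'
#' Centered moving average spanning `span_s` (30 s over 10 s windows = 3
#' windows). Edges average over the available shorter window set; missing
#' windows are skipped with renormalization. Smoothing never increases the
#' variance of the series.
#'
#' @param series A [respiratory_rate()] result.
#' @param span_s Averaging span, s.
#' @return The series with `smoothed_hz` filled in.
#' @export
smooth_rate <- function(series, span_s = 30) {
  stopifnot(inherits(series, "resp_rate_series"))
  window_s <- attr(series, "window_s")
  k <- max(1L, round(span_s / window_s))
  h <- k %/% 2
  n <- nrow(series)
  raw <- series$raw_hz
  series$smoothed_hz <- vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    v <- raw[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  series
}

#' Per-condition mean respiratory rate
#'
#' Mean of the smoothed rate over the windows whose centers fall inside
#' each protocol epoch (half-open membership).
#'
#' @param series A smoothed [respiratory_rate()] series.
#' @param timeline A [protocol_timeline()] on the same session clock.
#' @return Data frame `condition`, `t_start`, `t_end`, `mean_hz`,
#'   `mean_bpm`, `n_windows` (one row per epoch; `NA` with a warning when
#'   an epoch contains no window centers).
#' @export
epoch_mean_rate <- function(series, timeline) {
  stopifnot(inherits(series, "resp_rate_series"),
            inherits(timeline, "protocol_timeline"))
  rate <- if (all(is.na(series$smoothed_hz))) series$raw_hz else
    series$smoothed_hz
  ep <- timeline$epochs
  out <- ep
  out$mean_hz <- NA_real_
  out$n_windows <- 0L
  for (i in seq_len(nrow(ep))) {
    sel <- series$window_center_s >= ep$t_start[i] &
      series$window_center_s < ep$t_end[i]
    out$n_windows[i] <- sum(sel)
    if (!any(sel)) {
      warning("epoch ", ep$condition[i], " [", ep$t_start[i], ", ",
              ep$t_end[i], ") contains no rate windows")
      next
    }
    out$mean_hz[i] <- mean(rate[sel], na.rm = TRUE)
  }
  out$mean_bpm <- hz_to_bpm(out$mean_hz)
  out[c("condition", "t_start", "t_end", "mean_hz", "mean_bpm",
        "n_windows")]
}

#' Convert between Hz and breaths per minute
#'
#' Rates are carried internally in Hz; reports give both Hz and
#' breaths/minute (an exact factor of 60).
#'
#' @param hz,bpm Rate values.
#' @return The converted rate.
#' @export
hz_to_bpm <- function(hz) hz * 60

#' @rdname hz_to_bpm
#' @export
bpm_to_hz <- function(bpm) bpm / 60
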