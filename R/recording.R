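#' Multi-channel physiological recording
#'
#' A `swd_recording` bundles synchronized time series for one recording
#' session: epidural ECoG, nuchal EMG, plethysmography flow, chamber gas
#' concentrations, and the laser TTL line. All channels share one sampling
#' rate and one session clock with t = 0 at the first sample.
#'
#' @param channels Named list of equal-length numeric vectors. Names are
#'   channel roles, a subset of
#'   `c("ecog", "emg", "resp", "gas_o2", "gas_co2", "laser")`.
#'   At least one of `ecog` or `resp` must be present.
#' @param fs Sampling rate in Hz (default 200, the acquisition rate).
#' @param start_time Session-clock time of the first sample, in seconds.
#'
#' @return An object of class `swd_recording` with fields `channels`,
#'   `fs`, `start_time` and `duration` (seconds).
#' @export
recording <- function(channels, fs = 200, start_time = 0) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list of numeric vectors")
  }
  roles <- names(channels)
  unknown <- setdiff(roles, channel_roles())
  if (length(unknown) > 0) {
    stop("unknown channel role(s): ", paste(unknown, collapse = ", "),
         "; valid roles: ", paste(channel_roles(), collapse = ", "))
  }
  if (anyDuplicated(roles)) stop("channel roles must be unique")
  if (!any(c("ecog", "resp") %in% roles)) {
    stop("a recording needs at least one of the 'ecog' or 'resp' channels")
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all channels must have equal length; got lengths ",
         paste(lens, collapse = ", "))
  }
  if (lens[1] == 0L) stop("channels must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  channels <- lapply(channels, as.numeric)
  structure(
    list(channels = channels, fs = fs, start_time = as.numeric(start_time),
         duration = lens[[1]] / fs),
    class = "swd_recording"
  )
}

channel_roles <- function() {
  c("ecog", "emg", "resp", "gas_o2", "gas_co2", "laser")
}

#' @export
print.swd_recording <- function(x, ...) {
  cat("<swd_recording> ", format(x$duration), " s @ ", format(x$fs),
      " Hz (", length(x$channels[[1]]), " samples)\n", sep = "")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat("  start_time:", format(x$start_time), "s\n")
  invisible(x)
}

#' Sample times of a recording
#'
#' @param rec A [recording()].
#' @return Numeric vector of session-clock sample times in seconds.
#' @export
sample_times <- function(rec) {
  stopifnot(inherits(rec, "swd_recording"))
  n <- length(rec$channels[[1]])
  rec$start_time + (seq_len(n) - 1) / rec$fs
}

#' Read a recording from disk
#'
#' Supports EDF/EDF+ (`.edf`) and the package's plain-text table dialect
#' (`.csv`/`.txt`): a UTF-8 CSV with a mandatory header, a `time` column in
#' seconds, and one column per channel. All file-format decisions live here;
#' the analysis core only sees [recording()] objects.
#'
#' @param path File to read.
#' @param channel_map Named character vector mapping roles to channel names
#'   in the file, e.g. `c(ecog = "EEG1", emg = "EMG1", resp = "FLOW")`.
#'   When `NULL`, file channel names are taken as roles directly (columns
#'   that are not valid roles are ignored).
#' @return A [recording()].
#' @export
read_recording <- function(path, channel_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "edf") read_edf(path) else read_recording_table(path)
  avail <- names(raw$channels)
  if (is.null(channel_map)) {
    keep <- intersect(avail, channel_roles())
    if (length(keep) == 0) {
      stop("no channels named after a known role; supply `channel_map`. ",
           "Available channels: ", paste(avail, collapse = ", "))
    }
    channels <- raw$channels[keep]
  } else {
    if (is.null(names(channel_map))) {
      stop("`channel_map` must be a named vector: role -> channel name")
    }
    missing <- channel_map[!(channel_map %in% avail)]
    if (length(missing) > 0) {
      stop("channel(s) not found for role(s) ",
           paste(names(missing), collapse = ", "), ": requested ",
           paste(missing, collapse = ", "), "; available: ",
           paste(avail, collapse = ", "))
    }
    channels <- stats::setNames(raw$channels[channel_map], names(channel_map))
  }
  recording(channels, fs = raw$fs, start_time = raw$start_time)
}

#' Write a recording to disk
#'
#' The plain-text dialect round-trips samples exactly; EDF quantizes to
#' 16-bit integers, so samples round-trip within the per-channel
#' quantization step.
#'
#' @param rec A [recording()].
#' @param path Output path; format chosen by extension (`.edf` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "swd_recording"))
  if (length(rec$channels) == 0) stop("recording has no channels")
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") {
    write_edf(rec, path)
  } else {
    write_recording_table(rec, path)
  }
  invisible(path)
}

# Text dialect: header 'time,<role>,...', '.' decimal, %.17g so doubles
# round-trip bit-exactly.
write_recording_table <- function(rec, path) {
  tt <- sample_times(rec)
  cols <- c(list(time = tt), rec$channels)
  header <- paste(names(cols), collapse = ",")
  body <- do.call(paste, c(lapply(cols, function(v) sprintf("%.17g", v)),
                           sep = ","))
  writeLines(c(header, body), con = path, useBytes = TRUE)
  invisible(path)
}

read_recording_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("time" %in% names(df))) {
    stop("text recording must have a 'time' column (seconds)")
  }
  if (nrow(df) < 2) stop("text recording needs at least two samples")
  dt <- diff(df$time[1:2])
  if (dt <= 0) stop("'time' column must be strictly increasing")
  fs <- round(1 / dt, 6)
  chn <- df[setdiff(names(df), "time")]
  list(channels = as.list(chn), fs = fs, start_time = df$time[1])
}
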