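#' Coarse event annotations
#'
#' Coarse events are the manually identified seizure windows (blinded human
#' annotation in the original workflow) that the boundary refiner consumes.
#' They are stored as a data frame with columns `t_start`, `t_end` (seconds,
#' session clock) and `label`.
#'
#' @param t_start,t_end Numeric vectors of window bounds in seconds.
#' @param label Character vector of labels (recycled), default
#'   `"sws_candidate"`.
#' @return A data frame of class `coarse_events`.
#' @export
coarse_events <- function(t_start = numeric(), t_end = numeric(),
                          label = "sws_candidate") {
  if (length(t_start) != length(t_end)) {
    stop("`t_start` and `t_end` must have equal length")
  }
  bad <- which(t_end <= t_start)
  if (length(bad) > 0) {
    stop("t_end must exceed t_start; violated at row(s) ",
         paste(bad, collapse = ", "))
  }
  df <- data.frame(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                   label = rep_len(as.character(label),
                                   length.out = length(t_start)),
                   stringsAsFactors = FALSE)
  class(df) <- c("coarse_events", "data.frame")
  df
}

#' Read/write coarse event annotations (CSV)
#'
#' The CSV dialect has a mandatory header `t_start,t_end,label`, times in
#' seconds on the session clock. Write then read is the identity; row order
#' is preserved.
#'
#' @param path CSV file.
#' @return For `read_events`, a [coarse_events()] data frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_start", "t_end")
  if (!all(need %in% names(df))) {
    stop("event CSV must have header columns t_start,t_end,label")
  }
  if (!("label" %in% names(df))) df$label <- "sws_candidate"
  coarse_events(df$t_start, df$t_end, df$label)
}

#' @param events A [coarse_events()] data frame (or any data frame with
#'   columns `t_start`, `t_end`, `label`).
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("t_start", "t_end") %in% names(events)))
  if (!("label" %in% names(events))) events$label <- "sws_candidate"
  df <- data.frame(t_start = sprintf("%.17g", events$t_start),
                   t_end = sprintf("%.17g", events$t_end),
                   label = events$label)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Protocol timeline
#'
#' Ordered, non-overlapping condition epochs plus the alignment origin
#' `t_zero` (the gas-exchange or laser onset that peristimulus histograms
#' align to). Epoch membership is half-open: a time `t` belongs to the epoch
#' with `t_start <= t < t_end`.
#'
#' @param epochs Data frame with columns `t_start`, `t_end` (seconds) and
#'   `condition` (e.g. `"normoxia"`, `"hypoxia"`, `"hypoxia_co2"`,
#'   `"normoxia_co2"`, `"laser_on"`).
#' @param t_zero Alignment origin in seconds; must coincide with an epoch
#'   boundary.
#' @return An object of class `protocol_timeline`.
#' @export
protocol_timeline <- function(epochs, t_zero) {
  stopifnot(is.data.frame(epochs),
            all(c("t_start", "t_end", "condition") %in% names(epochs)))
  epochs <- epochs[order(epochs$t_start), , drop = FALSE]
  if (any(epochs$t_end <= epochs$t_start)) {
    stop("every epoch must have t_end > t_start")
  }
  if (nrow(epochs) > 1) {
    gap <- epochs$t_start[-1] - epochs$t_end[-nrow(epochs)]
    if (any(gap < -1e-9)) stop("epochs overlap")
  }
  bounds <- c(epochs$t_start, epochs$t_end)
  if (min(abs(bounds - t_zero)) > 1e-6) {
    stop("t_zero (", t_zero, " s) must coincide with an epoch boundary")
  }
  rownames(epochs) <- NULL
  structure(list(epochs = epochs, t_zero = as.numeric(t_zero)),
            class = "protocol_timeline")
}

#' @export
print.protocol_timeline <- function(x, ...) {
  cat("<protocol_timeline> t_zero =", x$t_zero, "s\n")
  print(x$epochs)
  invisible(x)
}

#' Condition in effect at given times
#'
#' @param timeline A [protocol_timeline()].
#' @param t Numeric vector of session-clock times (seconds).
#' @return Character vector of conditions (`NA` outside all epochs).
#' @export
condition_at <- function(timeline, t) {
  ep <- timeline$epochs
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(ep))) {
    out[t >= ep$t_start[i] & t < ep$t_end[i]] <- ep$condition[i]
  }
  out
}

#' Read/write a protocol timeline (JSON)
#'
#' @param path JSON file with fields `t_zero` and `epochs`
#'   (list of `{t_start, t_end, condition}`).
#' @return For `read_protocol`, a [protocol_timeline()].
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::fromJSON(path)
  if (is.null(js$t_zero) || is.null(js$epochs)) {
    stop("protocol JSON must have fields 't_zero' and 'epochs'")
  }
  protocol_timeline(as.data.frame(js$epochs), js$t_zero)
}

#' @param timeline A [protocol_timeline()].
#' @rdname read_protocol
#' @export
write_protocol <- function(timeline, path) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  jsonlite::write_json(list(t_zero = timeline$t_zero,
                            epochs = timeline$epochs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
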