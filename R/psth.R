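#' Align event onsets to a stimulus origin
#'
#' Events are referenced by onset throughout: an event straddling the
#' origin counts on the side of its onset, and an onset exactly at the
#' origin belongs to the post side (half-open bins).
#'
#' @param events Data frame with a `t_onset` column (a ground-truth event
#'   table with `t_start` is also accepted), or a numeric vector of onset
#'   times.
#' @param t_zero Alignment origin on the session clock, s.
#' @return Numeric vector of onset times relative to `t_zero`, s.
#' @export
align_events <- function(events, t_zero) {
  onsets <- if (is.numeric(events)) events
  else if ("t_onset" %in% names(events)) events$t_onset
  else if ("t_start" %in% names(events)) events$t_start
  else stop("`events` needs a t_onset (or t_start) column")
  onsets - t_zero
}

#' Peristimulus bin counts for one animal
#'
#' Counts event onsets in `2 * n_bins_per_side` half-open bins of width
#' `window_min / n_bins_per_side` covering `[-window_min, +window_min)`
#' minutes around the origin (default: three 5-min bins per side spanning
#' +/- 15 min). Onsets outside the span are ignored.
#'
#' @param rel_times Onset times relative to the origin, in seconds.
#' @param window_min Half-span of the histogram, minutes.
#' @param n_bins_per_side Bins on each side of the origin.
#' @return Integer vector of length `2 * n_bins_per_side`.
#' @export
bin_counts <- function(rel_times, window_min = 15, n_bins_per_side = 3) {
  if (window_min <= 0 || n_bins_per_side < 1) {
    stop("window_min and n_bins_per_side must be positive")
  }
  w <- window_min * 60
  bw <- w / n_bins_per_side
  nb <- 2L * n_bins_per_side
  idx <- floor((rel_times + w) / bw) + 1   # half-open [lo, hi) bins
  idx <- idx[rel_times >= -w & rel_times < w]
  counts <- tabulate(idx, nbins = nb)
  as.integer(counts)
}

#' Peristimulus time histogram across animals
#'
#' @param events_by_animal Named list of per-animal event tables (see
#'   [align_events()]), or a single pooled data frame with an `animal`
#'   column.
#' @param t_zero Alignment origin, s.
#' @param window_min,n_bins_per_side Histogram geometry (see
#'   [bin_counts()]).
#' @return Object of class `psth_result`: `counts` (animal x bin integer
#'   matrix), `bin_edges` (s, relative), `window_min`, `n_bins_per_side`.
#' @export
psth <- function(events_by_animal, t_zero, window_min = 15,
                 n_bins_per_side = 3) {
  if (is.data.frame(events_by_animal)) {
    if (!("animal" %in% names(events_by_animal))) {
      events_by_animal <- list(animal_1 = events_by_animal)
    } else {
      events_by_animal <- split(events_by_animal, events_by_animal$animal)
    }
  }
  counts <- t(vapply(events_by_animal, function(ev) {
    bin_counts(align_events(ev, t_zero), window_min, n_bins_per_side)
  }, integer(2L * n_bins_per_side)))
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("animal_", seq_len(nrow(counts)))
  }
  w <- window_min * 60
  edges <- seq(-w, w, length.out = 2L * n_bins_per_side + 1L)
  colnames(counts) <- sprintf("[%g,%g)", edges[-length(edges)] / 60,
                              edges[-1] / 60)
  structure(list(counts = counts, bin_edges = edges,
                 window_min = window_min,
                 n_bins_per_side = n_bins_per_side),
            class = "psth_result")
}

#' @export
print.psth_result <- function(x, ...) {
  cat("<psth_result> ", nrow(x$counts), " animal(s), ",
      ncol(x$counts), " bins of ",
      x$window_min / x$n_bins_per_side, " min\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Pre/post summaries of a PSTH
#'
#' Per animal, the total event count over the pre (`[-window, 0)`) and
#' post (`[0, +window)`) sides and the mean count per bin on each side;
#' across animals, the group mean and standard error (SD / sqrt(n),
#' animals being the experimental unit).
#'
#' @param x A [psth()] result or a bare counts matrix (animal x bin, pre
#'   bins first).
#' @return List with `per_animal` (data frame `animal`, `pre_total`,
#'   `post_total`, `mean_pre`, `mean_post`) and `group` (data frame
#'   `side`, `mean`, `se`, `n`).
#' @export
summarize_psth <- function(x) {
  counts <- if (inherits(x, "psth_result")) x$counts else as.matrix(x)
  nb <- ncol(counts) %/% 2L
  pre <- counts[, seq_len(nb), drop = FALSE]
  post <- counts[, nb + seq_len(nb), drop = FALSE]
  per_animal <- data.frame(
    animal = if (is.null(rownames(counts)))
      paste0("animal_", seq_len(nrow(counts))) else rownames(counts),
    pre_total = as.integer(rowSums(pre)),
    post_total = as.integer(rowSums(post)),
    mean_pre = rowSums(pre) / nb,
    mean_post = rowSums(post) / nb,
    stringsAsFactors = FALSE)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  group <- data.frame(
    side = c("pre", "post"),
    mean = c(mean(per_animal$mean_pre), mean(per_animal$mean_post)),
    se = c(se(per_animal$mean_pre), se(per_animal$mean_post)),
    n = nrow(counts))
  list(per_animal = per_animal, group = group)
}

#' Plot-ready stacked histogram table
#'
#' Long-format `(animal, bin, count)` table whose per-bin sums equal the
#' column sums of the counts matrix — the layout behind per-animal stacked
#' peristimulus histograms.
#'
#' @param x A [psth()] result or a counts matrix.
#' @return Data frame `animal`, `bin`, `bin_lo_min`, `bin_hi_min`, `count`.
#' @export
stacked_histogram <- function(x) {
  counts <- if (inherits(x, "psth_result")) x$counts else as.matrix(x)
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    return(data.frame(animal = character(), bin = integer(),
                      bin_lo_min = numeric(), bin_hi_min = numeric(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  edges <- if (inherits(x, "psth_result")) x$bin_edges / 60 else
    seq_len(ncol(counts) + 1L) - 1
  animals <- if (is.null(rownames(counts)))
    paste0("animal_", seq_len(nrow(counts))) else rownames(counts)
  data.frame(
    animal = rep(animals, times = ncol(counts)),
    bin = rep(seq_len(ncol(counts)), each = nrow(counts)),
    bin_lo_min = rep(edges[-length(edges)], each = nrow(counts)),
    bin_hi_min = rep(edges[-1], each = nrow(counts)),
    count = as.integer(as.vector(counts)),
    stringsAsFactors = FALSE)
}
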