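#' Pseudo-events spanning whole sequence presentations
#'
#' Collapses the four element events of each presentation of a sequence
#' into one window row (onset of the first element to offset of the last),
#' suitable as an [extract_trials()] selector for sequence-wide analyses
#' (time fields, within-sequence time decoding).
#'
#' @param events an `event_table`.
#' @param sequence sequence string.
#' @return data.frame of window rows with the event-table columns.
#' @export
sequence_windows <- function(events, sequence) {
  el <- events[events$kind == "element" & events$sequence == sequence, ,
               drop = FALSE]
  if (nrow(el) == 0) stop("no element events for sequence ", sequence)
  sp <- split(el, el$trial)
  out <- do.call(rbind, lapply(sp, function(d) {
    r <- d[1, ]
    r$onset_ms <- min(d$onset_ms)
    r$offset_ms <- max(d$offset_ms)
    r$element <- NA_character_
    r$position <- NA_integer_
    r
  }))
  out <- out[order(out$onset_ms), ]
  rownames(out) <- NULL
  out
}

#' Estimate per-cell time fields by even/odd consistency
#'
#' Splits trials into odd (1st, 3rd, ...) and even (2nd, 4th, ...) groups
#' by within-condition order, averages each group, and finds each cell's
#' peak frame in both half-averages (ties broken to the earliest frame).
#' A cell has a temporally consistent firing pattern iff the two peaks are
#' within `tolerance_frames` of each other (133 ms = 4 frames at 30 Hz);
#' consistent cells are assigned a time field from the all-trial average.
#' Cells with a flat (e.g. all-zero) half-average are inconsistent by
#' convention.
#'
#' @param tensor a `trial_tensor` aligned to the reference window
#'   (sequence, element, or gray).
#' @param tolerance_frames maximum |even peak - odd peak| for consistency.
#' @return data.frame (class `time_field_map`) with `cell`, `peak_even`,
#'   `peak_odd`, `consistent`, `peak` (all-trial peak frame, NA for
#'   inconsistent cells); frames are 1-based within the window. Attributes
#'   `n_frames`, `consistent_fraction`.
#' @export
estimate_time_fields <- function(tensor, tolerance_frames = 4L) {
  stopifnot(inherits(tensor, "trial_tensor"), dim(tensor)[2] >= 2)
  tr_even <- trial_average(tensor, "even")
  tr_odd <- trial_average(tensor, "odd")
  tr_all <- trial_average(tensor, "all")
  flat <- function(M) apply(M, 1, function(r) max(r) - min(r) <= 0)
  pk <- function(M) apply(M, 1, which.max)
  pe <- pk(tr_even); po <- pk(tr_odd)
  bad <- flat(tr_even) | flat(tr_odd)
  consistent <- !bad & abs(pe - po) <= tolerance_frames
  peak <- ifelse(consistent, pk(tr_all), NA_integer_)
  out <- data.frame(cell = seq_len(nrow(tr_all)), peak_even = pe,
                    peak_odd = po, consistent = consistent, peak = peak)
  attr(out, "n_frames") <- dim(tensor)[3]
  attr(out, "consistent_fraction") <- mean(consistent)
  attr(out, "tolerance_frames") <- as.integer(tolerance_frames)
  class(out) <- c("time_field_map", "data.frame")
  out
}

#' Peak-latency histogram and heatmap ordering
#'
#' Bins the assigned peak frames of consistent cells over the window. The
#' first `omit_after_onset` frames after each element onset can be omitted
#' (transmission-delay bins); cells peaking in omitted bins are dropped
#' from the histogram. Row order for heatmap display sorts cells by peak
#' frame with a stable sort (equal peaks keep input order); the
#' cross-validated display sorts by the even-half peak instead, so the
#' odd-half data shown are independent of the ordering.
#'
#' @param map a `time_field_map`.
#' @param element_onset_frames 1-based window frames at which elements
#'   start (e.g. `c(1, 8, 16, 23)` for a 30-frame sequence window at 30
#'   Hz); `NULL` for windows with no onset omission (gray periods).
#' @param omit_after_onset frames omitted after each listed onset.
#' @param sort_reference `"all"` (assigned peak) or `"even"`
#'   (cross-validated: sort on even, show odd).
#' @return list (class `latency_histogram`): `counts` (named integer per
#'   frame, NA at omitted frames), `order` (cell indices of consistent
#'   cells, sorted), `omitted_frames`, `n_cells`.
#' @export
latency_histogram <- function(map, element_onset_frames = NULL,
                              omit_after_onset = 2L,
                              sort_reference = c("all", "even")) {
  sort_reference <- match.arg(sort_reference)
  stopifnot(inherits(map, "time_field_map"))
  n_frames <- attr(map, "n_frames")
  keep <- map$consistent
  if (!any(keep)) stop("no consistent cells")
  omitted <- integer(0)
  if (!is.null(element_onset_frames) && omit_after_onset > 0) {
    omitted <- unique(unlist(lapply(element_onset_frames, function(f)
      f + seq_len(omit_after_onset) - 1L)))
    omitted <- omitted[omitted <= n_frames]
  }
  peaks <- map$peak[keep]
  use <- !(peaks %in% omitted)
  counts <- tabulate(peaks[use], nbins = n_frames)
  counts[omitted] <- NA_integer_
  names(counts) <- sprintf("f%02d", seq_len(n_frames))
  key <- if (sort_reference == "all") map$peak else map$peak_even
  cells <- map$cell[keep]
  ord <- cells[order(key[keep])]   # order() is stable: ties keep input order
  structure(list(counts = counts, order = ord, omitted_frames = omitted,
                 n_cells = sum(keep & use), sort_reference = sort_reference),
            class = "latency_histogram")
}

#' @export
print.latency_histogram <- function(x, ...) {
  cat(sprintf("<latency_histogram> %d cells over %d frames (%d omitted)\n",
              x$n_cells, length(x$counts), length(x$omitted_frames)))
  invisible(x)
}
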