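#' Cut an activity matrix into aligned trial windows
#'
#' Selects events from the table and extracts one window per event into a
#' cells x trials x frames tensor. Two offset conventions are supported:
#'
#' * `mode = "shift"`: the window starts `offset_frames` after the event's
#'   first frame and keeps the event's full frame count (the selectivity
#'   convention: the analysis window is still 250 ms / 800 ms long, shifted
#'   by the retino-cortical delay).
#' * `mode = "truncate"`: the first `offset_frames` frames are dropped and
#'   the window ends at the event offset (the prediction-error and
#'   correlation convention: "excluding the first ~66 ms").
#'
#' Because 250 ms elements alternate between 7 and 8 frames at 30 Hz, the
#' common window length is the minimum across selected events; all trials
#' therefore align exactly, at the cost of at most one trailing frame.
#'
#' @param activity an `activity_matrix` (cells x frames).
#' @param events an `event_table`.
#' @param selector logical vector over `events` rows, or a row data.frame
#'   subset of `events`, picking the events to align (one trial each).
#' @param offset_frames leading frames attributed to the information delay.
#' @param mode `"shift"` or `"truncate"` (see above).
#' @return a 3-d array (class `trial_tensor`) cells x trials x frames with
#'   attributes `trial_info` (the selected event rows, in session order),
#'   `offset_frames`, `mode`, `frame_rate`.
#' @export
extract_trials <- function(activity, events, selector,
                           offset_frames = 2L, mode = c("shift", "truncate")) {
  mode <- match.arg(mode)
  stopifnot(offset_frames >= 0)
  fr <- attr(activity, "frame_rate")
  if (is.null(fr)) fr <- attr(events, "frame_rate")
  sel <- if (is.data.frame(selector)) selector else events[selector, , drop = FALSE]
  if (nrow(sel) == 0) stop("selector matches no events")
  sel <- sel[order(sel$onset_ms), , drop = FALSE]

  wins <- lapply(seq_len(nrow(sel)), function(i) {
    w <- frames_for_event(sel$onset_ms[i], sel$offset_ms[i], fr, 0L)
    if (mode == "truncate") {
      if (w$first_frame + offset_frames >= w$last_frame) {
        stop("window empty after truncation")
      }
      c(w$first_frame + offset_frames, w$last_frame)
    } else {
      c(w$first_frame + offset_frames, w$last_frame + offset_frames)
    }
  })
  lens <- vapply(wins, function(w) w[2] - w[1], numeric(1))
  L <- min(lens)
  if (max(lens) - L > 1) {
    stop("ragged windows: lengths differ by more than one frame")
  }
  last_needed <- max(vapply(wins, function(w) w[1], numeric(1))) + L
  if (last_needed > ncol(activity)) {
    stop("window extends beyond activity matrix")
  }

  n_cells <- nrow(activity)
  tens <- array(0, dim = c(n_cells, nrow(sel), L))
  for (i in seq_len(nrow(sel))) {
    cols <- wins[[i]][1] + seq_len(L)  # 0-based first frame -> 1-based cols
    tens[, i, ] <- activity[, cols]
  }
  structure(tens, trial_info = sel, offset_frames = as.integer(offset_frames),
            mode = mode, frame_rate = fr,
            cell_meta = attr(activity, "cell_meta"),
            class = c("trial_tensor", "array"))
}

#' Time-average a trial tensor
#'
#' Unweighted mean over window frames per (cell, trial), yielding the
#' trials x cells response matrix used by selectivity, prediction-error,
#' correlation and decoding stages.
#'
#' @param tensor a `trial_tensor`.
#' @return a trials x cells matrix (class `response_matrix`) with attribute
#'   `trial_info`.
#' @export
time_average <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"), length(dim(tensor)) == 3)
  m <- rowMeans(tensor, dims = 2)         # cells x trials
  structure(t(m), trial_info = attr(tensor, "trial_info"),
            cell_meta = attr(tensor, "cell_meta"),
            class = c("response_matrix", "matrix", "array"))
}

#' Trial-average a tensor into a mean trace
#'
#' Mean over a subset of trials, returning the cells x frames average trace.
#' Subsets `"all"`, `"even"`, `"odd"` and `"first100"` refer to the
#' within-condition trial order (1st, 3rd, ... are odd).
#'
#' @param tensor a `trial_tensor`.
#' @param trials `"all"`, `"even"`, `"odd"`, `"first100"`, or an index vector.
#' @return cells x frames matrix.
#' @export
trial_average <- function(tensor, trials = "all") {
  stopifnot(inherits(tensor, "trial_tensor"))
  n <- dim(tensor)[2]
  idx <- if (is.character(trials)) {
    switch(trials,
           all = seq_len(n),
           even = seq_len(n)[seq_len(n) %% 2 == 0],
           odd = seq_len(n)[seq_len(n) %% 2 == 1],
           first100 = seq_len(min(100L, n)),
           stop("unknown trial subset: ", trials))
  } else {
    trials
  }
  if (length(idx) == 0) stop("empty trial subset")
  colMeans(aperm(tensor[, idx, , drop = FALSE], c(2, 1, 3)))
}

#' Export a response matrix to CSV (trial metadata + per-cell columns)
#' @param rm a `response_matrix`.
#' @param path file path.
#' @export
write_response_matrix <- function(rm, path) {
  info <- attr(rm, "trial_info")
  df <- cbind(info[, intersect(c("sequence", "element", "position", "block",
                                 "trial", "kind"), names(info)), drop = FALSE],
              as.data.frame(unclass(rm)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<trial_tensor> %d cells x %d trials x %d frames (%s, offset %d)\n",
              d[1], d[2], d[3], attr(x, "mode"), attr(x, "offset_frames")))
  invisible(x)
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d trials x %d cells\n", nrow(x), ncol(x)))
  invisible(x)
}
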