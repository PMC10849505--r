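#' Protocol configuration
#'
#' Describes one session of the sequence-learning stimulus: which grating
#' sequences are shown, element and gray durations, block structure, rest
#' periods and the acquisition frame rate.
#'
#' Defaults reproduce the standard design: three sequences (ABCD plus the
#' omission deviant ABBD and the substitution deviant ACBD) of 250 ms
#' elements followed by 800 ms of gray, shown in blocks of 100 presentations
#' with 10 s interblock rests, 5 blocks per sequence per day, and a 1-minute
#' gray period before and after the experiment, imaged at a nominal 30 Hz.
#'
#' @param sequences character vector of 4-letter sequence strings over the
#'   alphabet A--D.
#' @param element_ms duration of one grating element in ms (> 0).
#' @param gray_ms duration of the gray period following each presentation, ms.
#' @param block_size presentations per block.
#' @param blocks_per_sequence blocks of each sequence per session.
#' @param interblock_gap_ms rest period between blocks, ms.
#' @param lead_in_ms,lead_out_ms gray periods before/after the experiment, ms.
#' @param frame_rate acquisition frame rate, Hz.
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(sequences = c("ABCD", "ABBD", "ACBD"),
                            element_ms = 250,
                            gray_ms = 800,
                            block_size = 100,
                            blocks_per_sequence = 5,
                            interblock_gap_ms = 10000,
                            lead_in_ms = 60000,
                            lead_out_ms = 60000,
                            frame_rate = 30) {
  stopifnot(length(sequences) >= 1, element_ms > 0, gray_ms >= 0,
            block_size >= 0, blocks_per_sequence >= 0,
            interblock_gap_ms >= 0, lead_in_ms >= 0, lead_out_ms >= 0,
            frame_rate > 0)
  bad <- sequences[!grepl("^[ABCD]+$", sequences)]
  if (length(bad) > 0) {
    stop("sequence strings must use only letters A-D: ", paste(bad, collapse = ", "))
  }
  structure(list(sequences = sequences,
                 element_ms = element_ms,
                 gray_ms = gray_ms,
                 block_size = block_size,
                 blocks_per_sequence = blocks_per_sequence,
                 interblock_gap_ms = interblock_gap_ms,
                 lead_in_ms = lead_in_ms,
                 lead_out_ms = lead_out_ms,
                 frame_rate = frame_rate),
            class = "protocol_config")
}

#' Build the stimulus event table for one session
#'
#' Lays out every element, gray and rest event of a session on an exact
#' millisecond clock. Baseline and test days interleave one block of each
#' sequence per repetition (ABCD x block_size, ABBD x block_size, ...,
#' repeated `blocks_per_sequence` times); training days show only the first
#' configured sequence (ABCD). The construction is fully deterministic.
#'
#' @param config a [protocol_config()].
#' @param day one of `"baseline"`, `"training"`, `"test"`.
#' @return a `data.frame` (class `event_table`) with columns
#'   `kind` (element / gray / interblock), `sequence`, `element`, `position`,
#'   `block` (per-sequence repetition), `trial` (per-sequence presentation
#'   index), `presentation` (session-global presentation index), `onset_ms`,
#'   `offset_ms`. The frame rate is attached as attribute `frame_rate`.
#' @export
build_protocol <- function(config, day = c("baseline", "training", "test")) {
  stopifnot(inherits(config, "protocol_config"))
  day <- match.arg(day)
  seqs <- if (day == "training") config$sequences[1] else config$sequences

  rows <- list()
  t <- 0
  add <- function(kind, sequence, element, position, block, trial, presentation, dur) {
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, sequence = sequence, element = element,
      position = position, block = block, trial = trial,
      presentation = presentation,
      onset_ms = t, offset_ms = t + dur, stringsAsFactors = FALSE)
    t <<- t + dur
  }

  if (config$lead_in_ms > 0) {
    add("interblock", NA_character_, NA_character_, NA_integer_,
        NA_integer_, NA_integer_, NA_integer_, config$lead_in_ms)
  }

  trial_counter <- stats::setNames(integer(length(seqs)), seqs)
  presentation <- 0L
  n_blocks_total <- config$blocks_per_sequence * length(seqs)
  blk_i <- 0L
  for (rep_i in seq_len(config$blocks_per_sequence)) {
    for (s in seqs) {
      blk_i <- blk_i + 1L
      letters_s <- strsplit(s, "")[[1]]
      for (p in seq_len(config$block_size)) {
        trial_counter[s] <- trial_counter[s] + 1L
        presentation <- presentation + 1L
        for (pos in seq_along(letters_s)) {
          add("element", s, letters_s[pos], pos, rep_i,
              trial_counter[s], presentation, config$element_ms)
        }
        add("gray", s, NA_character_, NA_integer_, rep_i,
            trial_counter[s], presentation, config$gray_ms)
      }
      if (blk_i < n_blocks_total && config$interblock_gap_ms > 0) {
        add("interblock", NA_character_, NA_character_, NA_integer_,
            NA_integer_, NA_integer_, NA_integer_, config$interblock_gap_ms)
      }
    }
  }

  if (config$lead_out_ms > 0) {
    add("interblock", NA_character_, NA_character_, NA_integer_,
        NA_integer_, NA_integer_, NA_integer_, config$lead_out_ms)
  }

  tab <- if (length(rows) == 0) {
    data.frame(kind = character(), sequence = character(), element = character(),
               position = integer(), block = integer(), trial = integer(),
               presentation = integer(), onset_ms = numeric(), offset_ms = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  attr(tab, "frame_rate") <- config$frame_rate
  attr(tab, "day") <- day
  class(tab) <- c("event_table", "data.frame")
  tab
}

#' Frame window for one event
#'
#' Maps a millisecond event interval onto acquisition frames. Frame `f`
#' (0-based) covers the interval `[f * 1000/frame_rate, (f+1) * 1000/frame_rate)`
#' ms; a frame belongs to the event iff its start time lies in
#' `[onset, offset)`. The first `offset_frames` frames are then dropped,
#' which implements the ~67 ms (2-frame) retina-to-L2/3 information delay
#' in "truncate" mode.
#'
#' At 30 Hz the 250 ms elements alternate between 8 and 7 frames depending
#' on their onset phase; this is a property of the design, not an error.
#'
#' @param onset_ms,offset_ms event interval in ms (offset exclusive).
#' @param frame_rate frames per second.
#' @param offset_frames number of leading frames to drop (>= 0).
#' @return list with `first_frame` (inclusive), `last_frame` (exclusive),
#'   both 0-based, `n_frames`, and `offset_frames`. Class `frame_window`.
#' @export
frames_for_event <- function(onset_ms, offset_ms, frame_rate, offset_frames = 0L) {
  stopifnot(offset_frames >= 0, frame_rate > 0, offset_ms > onset_ms)
  dt <- frame_rate / 1000
  first <- as.integer(ceiling(onset_ms * dt - 1e-9))
  last <- as.integer(ceiling(offset_ms * dt - 1e-9))
  first <- first + as.integer(offset_frames)
  if (first >= last) {
    stop("window empty after dropping ", offset_frames,
         " frame(s): event too short for requested offset")
  }
  structure(list(first_frame = first, last_frame = last,
                 n_frames = last - first,
                 offset_frames = as.integer(offset_frames)),
            class = "frame_window")
}

#' Number of acquisition frames spanned by an event table
#' @param events an `event_table`.
#' @return integer frame count of the session.
#' @export
session_frames <- function(events) {
  if (nrow(events) == 0) return(0L)
  fr <- attr(events, "frame_rate")
  as.integer(ceiling(max(events$offset_ms) * fr / 1000 - 1e-9))
}

#' Validate a stimulus event table
#'
#' Checks structural invariants of an [build_protocol()] table: events are
#' non-overlapping and contiguous, per-sequence presentation counts equal
#' `block_size * blocks_per_sequence`, and every sequence presentation is
#' followed by exactly one gray event.
#'
#' @param events an `event_table`.
#' @param fatal if `TRUE`, stop on the first violation instead of reporting.
#' @return a `data.frame` of violations (zero rows when the table is valid),
#'   with columns `check` and `detail`.
#' @export
validate_protocol <- function(events, fatal = FALSE) {
  viol <- list()
  note <- function(check, detail) {
    viol[[length(viol) + 1]] <<- data.frame(check = check, detail = detail,
                                            stringsAsFactors = FALSE)
  }
  if (nrow(events) > 0) {
    o <- order(events$onset_ms)
    ev <- events[o, ]
    gaps <- ev$onset_ms[-1] - ev$offset_ms[-nrow(ev)]
    if (any(abs(gaps) > 1e-9)) {
      note("contiguity", sprintf("%d gap/overlap(s) between consecutive events",
                                 sum(abs(gaps) > 1e-9)))
    }
    if (any(ev$offset_ms <= ev$onset_ms)) {
      note("duration", "event with non-positive duration")
    }
    # every presentation must own exactly one gray event
    el <- ev[ev$kind == "element", ]
    gr <- ev[ev$kind == "gray", ]
    if (nrow(el) > 0) {
      pres <- unique(el[, c("sequence", "trial")])
      for (i in seq_len(nrow(pres))) {
        n_gray <- sum(gr$sequence == pres$sequence[i] & gr$trial == pres$trial[i],
                      na.rm = TRUE)
        if (n_gray != 1) {
          note("gray pairing", sprintf("presentation %s trial %d has %d gray event(s)",
                                       pres$sequence[i], pres$trial[i], n_gray))
        }
      }
      counts <- table(pres$sequence)
      if (length(unique(counts)) > 1) {
        note("balance", "unequal presentation counts across sequences")
      }
    }
  }
  out <- if (length(viol) == 0) {
    data.frame(check = character(), detail = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, viol)
  }
  if (fatal && nrow(out) > 0) {
    stop("protocol validation failed: ", out$check[1], " - ", out$detail[1])
  }
  out
}

#' Write / read an event table as CSV
#' @param events an `event_table`.
#' @param path file path.
#' @export
write_event_table <- function(events, path) {
  df <- as.data.frame(events)
  df$frame_rate <- attr(events, "frame_rate")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fr <- df$frame_rate[1]
  df$frame_rate <- NULL
  attr(df, "frame_rate") <- fr
  class(df) <- c("event_table", "data.frame")
  df
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events, %d presentation(s), %.1f s at %g Hz\n",
              nrow(x),
              if (nrow(x)) length(unique(stats::na.omit(x$presentation))) else 0L,
              if (nrow(x)) max(x$offset_ms) / 1000 else 0,
              attr(x, "frame_rate")))
  invisible(x)
}
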