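#' Per-condition response sets
#'
#' Builds one trials x cells time-averaged response matrix per stimulus
#' condition. With `context = "free"` the stimuli are the four gratings
#' A--D (pooling every occurrence across sequences and positions) plus the
#' full gray period. With `context = "context"` each element-in-sequence
#' condition (e.g. B in position 2 of ABCD) is its own stimulus -- 12
#' conditions for the standard three-sequence design -- plus one gray
#' condition per sequence.
#'
#' @param activity an `activity_matrix`.
#' @param events an `event_table`.
#' @param context `"free"` or `"context"`.
#' @param include_gray include gray-period condition(s).
#' @param offset_frames,mode window convention passed to [extract_trials()].
#' @return named list of `response_matrix` objects.
#' @export
stimulus_response_sets <- function(activity, events,
                                   context = c("free", "context"),
                                   include_gray = TRUE,
                                   offset_frames = 2L, mode = "shift") {
  context <- match.arg(context)
  out <- list()
  el <- events$kind == "element"
  if (context == "free") {
    for (letter in sort(unique(events$element[el]))) {
      sel <- el & events$element == letter
      out[[letter]] <- time_average(extract_trials(activity, events, sel,
                                                   offset_frames, mode))
    }
    if (include_gray && any(events$kind == "gray")) {
      out[["gray"]] <- time_average(extract_trials(activity, events,
                                                   events$kind == "gray",
                                                   offset_frames, mode))
    }
  } else {
    conds <- unique(events[el, c("sequence", "position", "element")])
    conds <- conds[order(conds$sequence, conds$position), ]
    for (i in seq_len(nrow(conds))) {
      sel <- el & events$sequence == conds$sequence[i] &
        events$position == conds$position[i]
      nm <- sprintf("%s.%d.%s", conds$sequence[i], conds$position[i],
                    conds$element[i])
      out[[nm]] <- time_average(extract_trials(activity, events, sel,
                                               offset_frames, mode))
    }
    if (include_gray && any(events$kind == "gray")) {
      for (s in sort(unique(events$sequence[events$kind == "gray"]))) {
        sel <- events$kind == "gray" & !is.na(events$sequence) &
          events$sequence == s
        out[[paste0(s, ".gray")]] <-
          time_average(extract_trials(activity, events, sel,
                                      offset_frames, mode))
      }
    }
  }
  out
}

#' Classify stimulus selectivity
#'
#' A cell is labeled selective for stimulus s when its mean response to s
#' exceeds the mean of the other stimuli by more than `k_sd` standard
#' deviations of the other stimuli. Two readings of "standard deviation of
#' the other stimuli" are supported:
#'
#' * `sd_mode = "trials"` (default): the SD of the pooled single-trial
#'   responses to the other stimuli. The threshold then reflects the
#'   trial-to-trial response variability, and a cell with identical
#'   response distributions across stimuli is selective only at the test's
#'   false-positive rate.
#' * `sd_mode = "stimulus_means"`: the SD across the other stimuli's mean
#'   responses (requires >= 2 other stimuli). This variant is scale-free in
#'   the spread of the means and is substantially more permissive on
#'   unresponsive cells.
#'
#' If several stimuli qualify the one with the largest response wins;
#' exact ties are labeled `"none"` (the deterministic replacement for
#' manual curation of mixed-selectivity cells).
#'
#' @param response_sets named list of `response_matrix` objects (one per
#'   stimulus), as from [stimulus_response_sets()]; or a cells x stimuli
#'   matrix of trial-averaged mean responses with column names (then only
#'   `sd_mode = "stimulus_means"` is possible).
#' @param k_sd selectivity threshold in SD units.
#' @param sd_mode reference-variability definition, see above.
#' @return data.frame (class `selectivity_table`) with `cell`, `label`
#'   (stimulus name or `"none"`), `margin` (response minus threshold for
#'   the winning stimulus), and the per-stimulus mean responses.
#' @export
classify_selectivity <- function(response_sets, k_sd = 2,
                                 sd_mode = c("trials", "stimulus_means")) {
  sd_mode <- match.arg(sd_mode)
  if (is.matrix(response_sets)) {
    if (sd_mode == "trials") {
      stop("sd_mode = \"trials\" needs per-trial response sets, not a mean matrix")
    }
    M <- response_sets
    ns <- NULL
  } else {
    M <- vapply(response_sets, colMeans, numeric(ncol(response_sets[[1]])))
    if (is.null(dim(M))) M <- matrix(M, nrow = 1,
                                     dimnames = list(NULL, names(response_sets)))
    ns <- vapply(response_sets, nrow, integer(1))
    Q <- vapply(response_sets, function(x) colSums(unclass(x)^2),
                numeric(nrow(M)))
    if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  }
  S <- ncol(M)
  if (S < 3) stop("need at least 3 stimuli (reference over at least 2 others)")
  n <- nrow(M)
  label <- rep("none", n)
  margin <- rep(NA_real_, n)

  # per-cell threshold matrix: thr[i, s] = mean(others) + k_sd * sd(others)
  thr <- matrix(NA_real_, n, S)
  for (s in seq_len(S)) {
    if (sd_mode == "stimulus_means") {
      mo <- rowMeans(M[, -s, drop = FALSE])
      so <- apply(M[, -s, drop = FALSE], 1, stats::sd)
    } else {
      N <- sum(ns[-s])
      Ssum <- M[, -s, drop = FALSE] %*% ns[-s]
      Qsum <- rowSums(Q[, -s, drop = FALSE])
      mo <- as.numeric(Ssum) / N
      so <- sqrt(pmax(0, (Qsum - N * mo^2) / (N - 1)))
    }
    thr[, s] <- mo + k_sd * so
  }
  for (i in seq_len(n)) {
    qual <- M[i, ] > thr[i, ]
    if (any(qual)) {
      cand <- which(qual)
      best <- cand[M[i, cand] == max(M[i, cand])]
      if (length(best) == 1) {
        label[i] <- colnames(M)[best]
        margin[i] <- M[i, best] - thr[i, best]
      }
    }
  }
  out <- data.frame(cell = seq_len(n), label = label, margin = margin,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(M))
  class(out) <- c("selectivity_table", "data.frame")
  out
}

#' Stimulus-driven flags (sparseness, strict measure)
#'
#' Flags a cell as driven by stimulus s when its trial- and time-averaged
#' response to s exceeds its overall mean rate by more than `k_sd` times
#' its overall SD, both computed across all time bins regardless of
#' stimulus. The first sparseness measure is the fraction of cells with at
#' least one flag. Zero-variance cells are flagged iff the response exceeds
#' the mean.
#'
#' @param stim_means cells x stimuli matrix of mean responses (e.g. from
#'   `sapply(stimulus_response_sets(...), colMeans)`).
#' @param overall_mean,overall_sd per-cell mean and SD across all frames of
#'   the activity matrix.
#' @param k_sd threshold in SD units.
#' @return list with `flags` (cells x stimuli logical matrix) and
#'   `driven_fraction` (scalar).
#' @export
stimulus_driven_flags <- function(stim_means, overall_mean, overall_sd,
                                  k_sd = 2) {
  stopifnot(nrow(stim_means) == length(overall_mean),
            length(overall_mean) == length(overall_sd))
  thr <- ifelse(overall_sd > 0, overall_mean + k_sd * overall_sd, overall_mean)
  flags <- sweep(stim_means, 1, thr, ">")
  list(flags = flags, driven_fraction = mean(rowSums(flags) >= 1))
}

#' Visual-modulation test (sparseness, permissive measure)
#'
#' Compares activity between grating and gray periods per cell: 266 ms
#' (8-frame) chunks are tiled within each grating span (the four-element
#' presentation period) and each gray span, consecutive chunks separated by
#' a 133 ms (4-frame) skipped gap to reduce serial correlation; the two
#' chunk-mean distributions are compared with a two-sample KS test.
#'
#' @param activity an `activity_matrix`.
#' @param events an `event_table`.
#' @param chunk_ms,gap_ms chunk and gap durations in ms.
#' @param alpha significance level; a cell is visually modulated iff the KS
#'   p-value falls below it.
#' @return list with `modulated` (logical per cell), `p` (per-cell KS
#'   p-values), and `modulated_fraction`.
#' @export
visual_modulation <- function(activity, events, chunk_ms = 266, gap_ms = 133,
                              alpha = 0.05) {
  fr <- attr(activity, "frame_rate")
  chunk_f <- max(1L, as.integer(round(chunk_ms * fr / 1000)))
  gap_f <- as.integer(round(gap_ms * fr / 1000))
  step <- chunk_f + gap_f

  chunk_cols <- function(spans) {
    # spans: data.frame onset_ms/offset_ms; returns list of column vectors.
    # The chunk/gap tiling phase rotates across spans so that every frame
    # of the span is sampled over the session (a fixed phase would leave
    # the same trailing frames of every span unsampled).
    cols <- list()
    for (i in seq_len(nrow(spans))) {
      w <- frames_for_event(spans$onset_ms[i], spans$offset_ms[i], fr, 0L)
      s <- w$first_frame + ((i - 1L) * gap_f) %% step
      while (s + chunk_f <= w$last_frame) {
        cols[[length(cols) + 1]] <- s + seq_len(chunk_f)  # 1-based columns
        s <- s + step
      }
    }
    cols
  }

  el <- events[events$kind == "element", , drop = FALSE]
  # grating span: contiguous element period of a presentation
  grat <- do.call(rbind, lapply(split(el, paste(el$sequence, el$trial)),
                                function(d) data.frame(onset_ms = min(d$onset_ms),
                                                       offset_ms = max(d$offset_ms))))
  gray <- events[events$kind == "gray", c("onset_ms", "offset_ms"), drop = FALSE]
  cg <- chunk_cols(grat)
  cy <- chunk_cols(gray)
  if (length(cg) < 2 || length(cy) < 2) stop("insufficient chunks per condition")

  mean_chunks <- function(cols) {
    vapply(cols, function(cc) rowMeans(activity[, cc, drop = FALSE]),
           numeric(nrow(activity)))
  }
  Mg <- mean_chunks(cg)   # cells x chunks (gratings)
  My <- mean_chunks(cy)
  p <- vapply(seq_len(nrow(activity)), function(i) {
    suppressWarnings(stats::ks.test(Mg[i, ], My[i, ])$p.value)
  }, numeric(1))
  list(modulated = p < alpha, p = p, modulated_fraction = mean(p < alpha))
}

#' Full selectivity table for one session
#'
#' Convenience wrapper running context-free and in-context selectivity
#' classification plus the stimulus-driven sparseness flags.
#'
#' @inheritParams stimulus_response_sets
#' @param k_sd threshold in SD units.
#' @param sd_mode reference-variability definition, see
#'   [classify_selectivity()].
#' @return a `selectivity_table` with added columns `context_label`,
#'   `driven` and attribute `summary` (counts and fractions per label).
#' @export
selectivity_table <- function(activity, events, k_sd = 2,
                              sd_mode = c("trials", "stimulus_means"),
                              offset_frames = 2L, mode = "shift") {
  sd_mode <- match.arg(sd_mode)
  free_sets <- stimulus_response_sets(activity, events, "free",
                                      offset_frames = offset_frames, mode = mode)
  ctx_sets <- stimulus_response_sets(activity, events, "context",
                                     offset_frames = offset_frames, mode = mode)
  tab <- classify_selectivity(free_sets, k_sd, sd_mode)
  ctx <- classify_selectivity(ctx_sets, k_sd, sd_mode)
  tab$context_label <- ctx$label
  mu <- rowMeans(activity)
  sdv <- apply(activity, 1, stats::sd)
  stim_means <- vapply(free_sets, colMeans, numeric(ncol(free_sets[[1]])))
  drv <- stimulus_driven_flags(stim_means, mu, sdv, k_sd)
  tab$driven <- rowSums(drv$flags) >= 1
  counts <- table(factor(tab$label, levels = c(names(free_sets), "none")))
  attr(tab, "summary") <- data.frame(stimulus = names(counts),
                                     count = as.integer(counts),
                                     fraction = as.numeric(counts) / nrow(tab))
  attr(tab, "driven_fraction") <- drv$driven_fraction
  tab
}
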