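#' PCA untangling of sequence-mean population trajectories
#'
#' Concatenates the trial-averaged traces of all sequences along time into
#' a time x cell matrix, centers each cell, and decomposes it. The scores
#' are re-split by sequence so the behaviour of the shared components
#' during each sequence can be compared (after training the leading
#' components align with individual stimuli; before training they mix).
#' Only centering is applied -- deconvolved amplitudes are kept on their
#' native scale.
#'
#' @param traces named list of cells x frames trial-averaged traces, one
#'   per sequence, over a common cell set.
#' @param var_threshold cumulative explained-variance target.
#' @return list (class `pca_decomposition`): `scores` (named list of
#'   frames x component matrices per sequence), `var_ratio`
#'   (explained-variance ratios), `n_components` (count reaching
#'   `var_threshold`), `rotation`.
#' @export
pca_untangle <- function(traces, var_threshold = 0.9) {
  stopifnot(is.list(traces), length(traces) >= 1)
  n_cells <- unique(vapply(traces, nrow, integer(1)))
  if (length(n_cells) != 1) stop("traces must share a common cell set")
  if (n_cells < 2) stop("need at least 2 cells")
  X <- do.call(rbind, lapply(traces, t))   # (total frames) x cells
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  n_comp <- which(cumsum(var_ratio) >= var_threshold - 1e-12)[1]
  lens <- vapply(traces, ncol, integer(1))
  idx <- split(seq_len(sum(lens)), rep(seq_along(lens), lens))
  scores <- lapply(idx, function(i) pc$x[i, , drop = FALSE])
  names(scores) <- names(traces)
  structure(list(scores = scores, var_ratio = var_ratio,
                 n_components = n_comp, rotation = pc$rotation,
                 var_threshold = var_threshold),
            class = "pca_decomposition")
}

#' @export
print.pca_decomposition <- function(x, ...) {
  cat(sprintf("<pca_decomposition> %d components to reach %.0f%% variance (PC1 %.1f%%)\n",
              x$n_components, 100 * x$var_threshold, 100 * x$var_ratio[1]))
  invisible(x)
}

# row-wise Pearson correlation of two matrices; rows with zero variance -> NA
row_cor <- function(X, Y) {
  n <- ncol(X)
  mx <- rowMeans(X); my <- rowMeans(Y)
  cx <- X - mx; cy <- Y - my
  sx <- sqrt(rowSums(cx^2)); sy <- sqrt(rowSums(cy^2))
  r <- rowSums(cx * cy) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  r
}

#' Within-presentation element correlations
#'
#' For every presentation of one sequence, time-averages the population
#' vector of each of the four elements (dropping the first `offset_frames`
#' frames after each element onset) and computes the Pearson correlation of
#' all 6 unordered element pairs. A full standard session yields
#' 500 presentations x 6 pairs = 3000 coefficients per sequence.
#' Zero-variance vectors make their pairs NA; these are dropped from the
#' distribution and counted.
#'
#' @param activity an `activity_matrix`.
#' @param events an `event_table`.
#' @param sequence sequence string, e.g. `"ABCD"`.
#' @param offset_frames leading frames dropped from each element window.
#' @return data.frame (class `correlation_set`) with `trial`, `pair`
#'   (e.g. `"1-2"`), `r`; attribute `n_dropped`.
#' @export
element_correlations <- function(activity, events, sequence,
                                 offset_frames = 2L) {
  el <- events$kind == "element" & events$sequence == sequence
  if (!any(el)) stop("no element events for sequence ", sequence)
  positions <- sort(unique(events$position[el]))
  resp <- lapply(positions, function(p) {
    time_average(extract_trials(activity, events, el & events$position == p,
                                offset_frames, "truncate"))
  })
  n_trials <- nrow(resp[[1]])
  pairs <- utils::combn(seq_along(positions), 2)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    r <- row_cor(resp[[i]], resp[[j]])
    out[[k]] <- data.frame(trial = seq_len(n_trials),
                           pair = sprintf("%d-%d", positions[i], positions[j]),
                           r = r, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  n_dropped <- sum(is.na(out$r))
  out <- out[order(out$trial, out$pair), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "sequence") <- sequence
  class(out) <- c("correlation_set", "data.frame")
  out
}

#' Representational-drift curve
#'
#' Computes the Pearson correlation between the population response vectors
#' of every trial pair of one stimulus, groups the coefficients by the
#' trial distance |i - j| into bins, and returns the mean per bin. Stable
#' representations give a flat curve; multiplicative-gain drift gives a
#' decline with distance.
#'
#' @param responses trials x cells `response_matrix` for one stimulus, in
#'   session order.
#' @param bin_width trial-distance bin width.
#' @param blocks optional block index per trial; when given, pairs
#'   straddling blocks are flagged and can be excluded.
#' @param within_block_only drop cross-block pairs.
#' @return data.frame (class `drift_curve`) with `bin`, `dist_lo`,
#'   `dist_hi`, `mean_r`, `n_pairs`.
#' @export
drift_curve <- function(responses, bin_width = 50, blocks = NULL,
                        within_block_only = FALSE) {
  n <- nrow(responses)
  stopifnot(n >= 2)
  C <- suppressWarnings(stats::cor(t(responses)))
  ut <- which(upper.tri(C), arr.ind = TRUE)
  d <- ut[, 2] - ut[, 1]
  r <- C[ut]
  keep <- !is.na(r)
  if (within_block_only && !is.null(blocks)) {
    keep <- keep & blocks[ut[, 1]] == blocks[ut[, 2]]
  }
  d <- d[keep]; r <- r[keep]
  max_d <- max(d)
  edges <- seq(1, max_d + bin_width, by = bin_width)
  bin <- findInterval(d, edges)
  agg <- tapply(r, bin, mean)
  cnt <- tapply(r, bin, length)
  bins <- as.integer(names(agg))
  out <- data.frame(bin = bins,
                    dist_lo = edges[bins],
                    dist_hi = pmin(edges[bins] + bin_width - 1, max_d),
                    mean_r = as.numeric(agg),
                    n_pairs = as.integer(cnt))
  class(out) <- c("drift_curve", "data.frame")
  out
}
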