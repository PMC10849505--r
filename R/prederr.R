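#' Per-cell prediction-error ratios
#'
#' The PE ratio of a cell is its trial- and time-averaged activity during
#' the deviant window divided by that during the standard window. Cells
#' whose standard-window mean does not exceed `eps` (by default 1e-6 of the
#' population mean amplitude over both windows) are excluded for ratio
#' stability and counted in the result.
#'
#' @param deviant,standard trials x cells `response_matrix` objects for the
#'   deviant and standard windows (same cells, same order).
#' @param cells optional integer vector restricting to a responsive subset.
#' @param eps_frac exclusion threshold as a fraction of the population mean.
#' @return data.frame (class `pe_result`) with `cell`, `deviant_mean`,
#'   `standard_mean`, `ratio` (NA when excluded), `excluded`; attributes
#'   `n` (retained cells) and `mean_ratio`.
#' @export
pe_ratio <- function(deviant, standard, cells = NULL, eps_frac = 1e-6) {
  stopifnot(ncol(deviant) == ncol(standard))
  if (is.null(cells)) cells <- seq_len(ncol(deviant))
  dm <- colMeans(deviant[, cells, drop = FALSE])
  sm <- colMeans(standard[, cells, drop = FALSE])
  eps <- eps_frac * mean(c(dm, sm))
  excl <- sm <= eps
  ratio <- ifelse(excl, NA_real_, dm / sm)
  out <- data.frame(cell = cells, deviant_mean = dm, standard_mean = sm,
                    ratio = ratio, excluded = excl)
  attr(out, "n") <- sum(!excl)
  attr(out, "mean_ratio") <- mean(ratio[!excl])
  class(out) <- c("pe_result", "data.frame")
  out
}

#' Omission / substitution prediction-error analysis for one session
#'
#' Runs the full PE design on an activity matrix: classifies stimulus
#' selectivity (context-free), restricts to the responsive set, extracts
#' the deviant and standard windows with the 2-frame information-delay
#' truncation, and computes per-cell PE ratios.
#'
#' Designs (window identities follow the element letter):
#' * `omission`: B-responsive cells; deviant = held B (position 3 of ABBD),
#'   standard = B in position 2 of ABBD (`standard_variant = "ABBD"`) or of
#'   ABCD (`"ABCD"`).
#' * `substitution`: C-responsive cells; deviant = C in position 2 of ACBD,
#'   standard = C in position 3 of ABCD.
#'
#' @param activity an `activity_matrix`.
#' @param events an `event_table` for the same session.
#' @param design `"omission"` or `"substitution"`.
#' @param standard_variant standard element for the omission design.
#' @param selectivity optional precomputed `selectivity_table`; recomputed
#'   from this session otherwise (responsive sets are per-day).
#' @param offset_frames information-delay frames dropped from each window.
#' @param k_sd selectivity threshold.
#' @return a `pe_result` (see [pe_ratio()]) with attribute `design`.
#' @export
pe_analysis <- function(activity, events,
                        design = c("omission", "substitution"),
                        standard_variant = c("ABBD", "ABCD"),
                        selectivity = NULL, offset_frames = 2L, k_sd = 2) {
  design <- match.arg(design)
  standard_variant <- match.arg(standard_variant)
  if (is.null(selectivity)) {
    sets <- stimulus_response_sets(activity, events, "free",
                                   offset_frames = offset_frames)
    selectivity <- classify_selectivity(sets, k_sd)
  }
  sel_for <- function(seq, pos) {
    events$kind == "element" & events$sequence == seq & events$position == pos
  }
  if (design == "omission") {
    cells <- which(selectivity$label == "B")
    dev_sel <- sel_for("ABBD", 3)
    std_sel <- sel_for(standard_variant, 2)
  } else {
    cells <- which(selectivity$label == "C")
    dev_sel <- sel_for("ACBD", 2)
    std_sel <- sel_for("ABCD", 3)
  }
  if (length(cells) == 0) stop("no responsive cells for design ", design)
  dev <- time_average(extract_trials(activity, events, dev_sel,
                                     offset_frames, "truncate"))
  std <- time_average(extract_trials(activity, events, std_sel,
                                     offset_frames, "truncate"))
  out <- pe_ratio(dev, std, cells)
  attr(out, "design") <- design
  attr(out, "standard_variant") <-
    if (design == "omission") standard_variant else "ABCD"
  out
}

#' Compare PE-ratio distributions between days
#'
#' Two-sample KS test on the pooled per-cell ratio samples. `n` is reported
#' as the combined sample size.
#'
#' @param pe_day0,pe_day5 `pe_result` objects or numeric ratio vectors.
#' @return list with `statistic`, `p.value`, `n`, `mean_day0`, `mean_day5`.
#' @export
compare_days <- function(pe_day0, pe_day5) {
  r0 <- if (is.data.frame(pe_day0)) pe_day0$ratio[!pe_day0$excluded] else pe_day0
  r5 <- if (is.data.frame(pe_day5)) pe_day5$ratio[!pe_day5$excluded] else pe_day5
  stopifnot(length(r0) > 0, length(r5) > 0)
  kt <- suppressWarnings(stats::ks.test(r0, r5))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       n = length(r0) + length(r5),
       mean_day0 = mean(r0), mean_day5 = mean(r5))
}

#' Hierarchical (mouse-then-cell) bootstrap
#'
#' Nonparametric bootstrap for nested data: each iteration resamples mice
#' with replacement (keeping the mouse count), pools the cells of the
#' sampled mice, resamples cells with replacement to the pool size, and
#' stores the mean. Applies to scalar per-cell statistics (e.g. PE ratios)
#' and to per-cell traces (cells x frames matrices, giving a mean trace per
#' iteration).
#'
#' @param values numeric vector (one value per cell) or cells x frames
#'   matrix of traces.
#' @param mouse mouse id per cell (same length/rows as `values`).
#' @param n_iter bootstrap iterations.
#' @param seed optional RNG seed.
#' @param probs confidence-band percentiles.
#' @return object of class `bootstrap_result`: list with `iterations`
#'   (n_iter x dims matrix of means), `median`, `ci` (2 x dims), `n_iter`.
#' @export
hierarchical_bootstrap <- function(values, mouse, n_iter = 1000, seed = NULL,
                                   probs = c(0.025, 0.975)) {
  V <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  stopifnot(nrow(V) == length(mouse), nrow(V) > 0, n_iter >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mice <- unique(mouse)
  rows_by_mouse <- split(seq_len(nrow(V)), mouse)
  iters <- matrix(NA_real_, n_iter, ncol(V))
  for (it in seq_len(n_iter)) {
    ms <- sample(mice, length(mice), replace = TRUE)
    pool <- unlist(rows_by_mouse[as.character(ms)], use.names = FALSE)
    draw <- pool[sample.int(length(pool), length(pool), replace = TRUE)]
    iters[it, ] <- colMeans(V[draw, , drop = FALSE])
  }
  med <- apply(iters, 2, stats::median)
  ci <- apply(iters, 2, stats::quantile, probs = probs)
  structure(list(iterations = iters, median = med, ci = ci, n_iter = n_iter),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  d <- ncol(x$iterations)
  if (d == 1) {
    cat(sprintf("<bootstrap_result> %d iterations: median %.4g [%.4g, %.4g]\n",
                x$n_iter, x$median, x$ci[1, 1], x$ci[2, 1]))
  } else {
    cat(sprintf("<bootstrap_result> %d iterations over %d points\n",
                x$n_iter, d))
  }
  invisible(x)
}

#' Screen for exclusive "prediction-error cells"
#'
#' Flags cells that are active in the deviant window (mean above their
#' overall mean + `k_sd` SD across all frames) while staying near baseline
#' (below overall mean + `k_other` SD) in every other element-in-sequence
#' and gray condition -- cells firing exclusively during the expectation
#' violation. The silence bar is deliberately lower than the activity bar:
#' a cell with clear but sub-threshold responses elsewhere is not an
#' exclusive deviant responder.
#'
#' @inheritParams pe_analysis
#' @param k_sd activity threshold for the deviant window, in across-frame
#'   SD units.
#' @param k_other silence threshold for all other conditions.
#' @return list with `cells` (indices) and `count`.
#' @export
exclusive_deviant_cells <- function(activity, events,
                                    design = c("omission", "substitution"),
                                    offset_frames = 2L, k_sd = 2,
                                    k_other = 1) {
  design <- match.arg(design)
  sets <- stimulus_response_sets(activity, events, "context",
                                 offset_frames = offset_frames)
  dev_name <- if (design == "omission") "ABBD.3.B" else "ACBD.2.C"
  if (!dev_name %in% names(sets)) stop("deviant condition not in session")
  M <- vapply(sets, colMeans, numeric(ncol(sets[[1]])))
  mu <- rowMeans(activity)
  sdv <- apply(activity, 1, stats::sd)
  others <- setdiff(colnames(M), dev_name)
  hit <- M[, dev_name] > mu + k_sd * sdv &
    rowSums(M[, others, drop = FALSE] > mu + k_other * sdv) == 0
  list(cells = which(hit), count = sum(hit))
}
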