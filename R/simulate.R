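#' Generator configuration for synthetic deconvolved population activity
#'
#' Parameterizes a synthetic population that emulates the statistical
#' structure of deconvolved two-photon activity under the sequence paradigm:
#' element-selective cells (fractions per day following the observed
#' selectivity table), gray-onset cells responding ~300 ms into the
#' intersequence gray period, gray-ramp cells whose activity climbs toward
#' the end of the gray period, and unresponsive background cells. Planted
#' effects: a day-specific omission-response multiplier on held-B activity,
#' a day-specific substitution gain on C-in-ACBD activity, day-specific
#' response-latency distributions (late-skewed at baseline, bimodal
#' onset/offset-locked after training), and slow multiplicative drift.
#'
#' @param n_mice number of mice.
#' @param cells_per_mouse cells recorded per mouse.
#' @param class_fractions named list with entries `day0` and `day5`, each a
#'   named numeric vector of fractions for classes `A`, `B`, `C`, `D`,
#'   `gray_onset`, `gray_ramp` (remainder = background). Defaults follow the
#'   observed day-0/day-5 selectivity fractions, with gray-responsive cells
#'   split 2:1 between onset and ramping subtypes.
#' @param latency list with per-day latency-distribution parameters. Day-0
#'   latencies are Beta-skewed toward late times within the element
#'   (density increasing over the post-delay window); day-5 latencies are a
#'   50/50 bimodal Beta mixture concentrated near element onset and offset.
#' @param latency_offset_ms retino-cortical information delay, ms. Element
#'   latencies are drawn above this delay.
#' @param amplitude median evoked bump amplitude, a.u.
#' @param amplitude_sdlog log-normal spread of per-cell amplitudes.
#' @param sigma_ms element-response bump width (Gaussian SD), ms.
#' @param gray_sigma_ms gray-onset bump width, ms.
#' @param gray_latency_ms,gray_latency_sd_ms gray-onset latency distribution.
#' @param baseline baseline rate added to every frame, a.u./frame.
#' @param omission_gain named per-day multiplier rho applied to B-cell
#'   activity in the held-B (position 3 of ABBD) window; calibrated so the
#'   expected omission PE ratio equals rho.
#' @param substitution_gain named per-day multiplier applied to C-cell
#'   activity in the unexpected (position 2 of ACBD) window relative to the
#'   expected C-in-ABCD response.
#' @param drift_eta volatility of the per-cell multiplicative gain random
#'   walk over presentations (gain = exp(eta * W_t)).
#' @param latency_swap_frac fraction of cells whose preferred latency
#'   crossfades to a second random latency over the session (rotation-like
#'   drift component).
#' @param noise_sd additive Gaussian frame noise SD before truncation at 0.
#' @param seed master seed; per-stage child seeds are derived from it.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_mice = 8,
                             cells_per_mouse = 171,
                             class_fractions = list(
                               day0 = c(A = 0.061, B = 0.100, C = 0.061,
                                        D = 0.092, gray_onset = 0.063,
                                        gray_ramp = 0.031),
                               day5 = c(A = 0.027, B = 0.071, C = 0.026,
                                        D = 0.043, gray_onset = 0.069,
                                        gray_ramp = 0.034)),
                             latency = list(
                               day0 = list(kind = "late", shape1 = 2.5, shape2 = 1),
                               day5 = list(kind = "bimodal",
                                           early = c(1, 5), late = c(5, 1),
                                           w_early = 0.5)),
                             latency_offset_ms = 67,
                             amplitude = 5,
                             amplitude_sdlog = 0.2,
                             sigma_ms = 60,
                             gray_sigma_ms = 80,
                             gray_latency_ms = 300,
                             gray_latency_sd_ms = 40,
                             baseline = 0.05,
                             omission_gain = c(day0 = 1.10, day5 = 1.44),
                             substitution_gain = c(day0 = 0.88, day5 = 0.84),
                             drift_eta = 0.01,
                             latency_swap_frac = 0,
                             noise_sd = 0.5,
                             seed = 1) {
  for (d in names(class_fractions)) {
    if (sum(class_fractions[[d]]) > 1 + 1e-9) {
      stop("class fractions for ", d, " sum to more than 1")
    }
  }
  stopifnot(amplitude >= 0, sigma_ms > 0, gray_sigma_ms > 0, baseline >= 0,
            all(omission_gain >= 0), all(substitution_gain >= 0),
            drift_eta >= 0, noise_sd >= 0,
            latency_swap_frac >= 0, latency_swap_frac <= 1)
  structure(list(n_mice = n_mice, cells_per_mouse = cells_per_mouse,
                 class_fractions = class_fractions, latency = latency,
                 latency_offset_ms = latency_offset_ms,
                 amplitude = amplitude, amplitude_sdlog = amplitude_sdlog,
                 sigma_ms = sigma_ms, gray_sigma_ms = gray_sigma_ms,
                 gray_latency_ms = gray_latency_ms,
                 gray_latency_sd_ms = gray_latency_sd_ms,
                 baseline = baseline, omission_gain = omission_gain,
                 substitution_gain = substitution_gain,
                 drift_eta = drift_eta, latency_swap_frac = latency_swap_frac,
                 noise_sd = noise_sd, seed = seed),
            class = "generator_config")
}

# deterministic child seed per stage/day, kept below 2^31
child_seed <- function(seed, stage, day) {
  stages <- c(population = 1L, session = 2L, noise = 3L)
  days <- c(day0 = 1L, day5 = 2L)
  (as.integer(seed) %% 1000000L) * 1000L + stages[[stage]] * 10L + days[[day]]
}

draw_element_latency <- function(n, cfg, day) {
  lp <- cfg$latency[[day]]
  lo <- cfg$latency_offset_ms
  span <- 250 - lo
  if (lp$kind == "late") {
    lo + span * stats::rbeta(n, lp$shape1, lp$shape2)
  } else {
    early <- stats::runif(n) < lp$w_early
    x <- numeric(n)
    x[early] <- stats::rbeta(sum(early), lp$early[1], lp$early[2])
    x[!early] <- stats::rbeta(sum(!early), lp$late[1], lp$late[2])
    lo + span * x
  }
}

#' Generate a synthetic cell population
#'
#' Draws per-cell ground truth (class, amplitude, latency, bump width,
#' baseline, planted gains) for one imaging day. Class membership is
#' multinomial around the configured fractions; latencies follow the
#' day-specific distribution.
#'
#' @param config a [generator_config()].
#' @param day `"day0"` or `"day5"`.
#' @return a `data.frame` (class `cell_spec`) with one row per cell:
#'   `mouse`, `cell`, `class`, `amplitude`, `latency_ms`, `latency2_ms`,
#'   `sigma_ms`, `baseline`, `omission_gain`, `substitution_gain`, `swap`.
#' @export
generate_population <- function(config, day = c("day0", "day5")) {
  stopifnot(inherits(config, "generator_config"))
  day <- match.arg(day)
  fr <- config$class_fractions[[day]]
  if (is.null(fr)) stop("no class fractions configured for ", day)
  if (sum(fr) > 1 + 1e-9) stop("class fractions sum to more than 1")
  set.seed(child_seed(config$seed, "population", day))

  n <- config$n_mice * config$cells_per_mouse
  classes <- c(names(fr), "background")
  probs <- c(fr, background = 1 - sum(fr))
  cls <- sample(classes, n, replace = TRUE, prob = probs)

  lat <- rep(NA_real_, n)
  elem <- cls %in% c("A", "B", "C", "D")
  lat[elem] <- draw_element_latency(sum(elem), config, day)
  gon <- cls == "gray_onset"
  lat[gon] <- pmin(pmax(stats::rnorm(sum(gon), config$gray_latency_ms,
                                     config$gray_latency_sd_ms), 80), 700)
  sig <- ifelse(elem, config$sigma_ms, config$gray_sigma_ms)
  lat2 <- rep(NA_real_, n)
  swap <- rep(FALSE, n)
  if (config$latency_swap_frac > 0) {
    swap <- elem & stats::runif(n) < config$latency_swap_frac
    lat2[swap] <- draw_element_latency(sum(swap), config, day)
  }
  spec <- data.frame(
    mouse = rep(seq_len(config$n_mice), each = config$cells_per_mouse),
    cell = seq_len(n),
    class = cls,
    amplitude = config$amplitude *
      exp(stats::rnorm(n, 0, config$amplitude_sdlog)),
    latency_ms = lat,
    latency2_ms = lat2,
    sigma_ms = sig,
    baseline = config$baseline,
    omission_gain = unname(config$omission_gain[day]),
    substitution_gain = unname(config$substitution_gain[day]),
    swap = swap,
    stringsAsFactors = FALSE)
  attr(spec, "day") <- day
  class(spec) <- c("cell_spec", "data.frame")
  spec
}

# expected value of max(0, X), X ~ N(mu, sd); the mean of truncated
# additive noise seen by every window average
truncated_mean <- function(mu, sd) {
  if (sd <= 0) return(pmax(mu, 0))
  mu * stats::pnorm(mu / sd) + sd * stats::dnorm(mu / sd)
}

# solve for k so that mean(truncated_mean(k*shape + base, sd)) = target
calibrate_gain <- function(shape, base, sd, target) {
  if (all(shape <= 0)) return(0)
  f <- function(k) mean(truncated_mean(k * shape + base, sd)) - target
  if (f(0) >= 0) return(0)
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-10)$root
}

# frame start times (ms) of the analysis window of an element occupying
# [onset, onset+250) relative to presentation start, truncate mode, 2 frames
pe_window_frames <- function(rel_onset_ms, element_ms, frame_rate,
                             offset_frames = 2L) {
  w <- frames_for_event(rel_onset_ms, rel_onset_ms + element_ms, frame_rate,
                        offset_frames)
  seq(w$first_frame, w$last_frame - 1L)
}

#' Simulate one session of deconvolved population activity
#'
#' Renders a cells-by-frames nonnegative activity matrix for the given
#' event table. Each driving event of a cell's class contributes
#' `g_t * amplitude * exp(-(t - (onset + latency))^2 / (2 sigma^2))`
#' evaluated at frame start times within the event window, where
#' `g_t = exp(eta * W_t)` is the cell's multiplicative gain random walk
#' over session presentations. B-cells additionally emit activity in the
#' held-B window (position 3 of ABBD) scaled so that the expected
#' time-averaged omission ratio equals the planted `omission_gain`;
#' C-cells in the unexpected ACBD position are scaled analogously by
#' `substitution_gain` relative to the expected C-in-ABCD response.
#' Gray-onset cells emit a bump after gray onset; gray-ramp cells emit
#' activity rising linearly to gray offset. Gaussian frame noise is added
#' and the matrix truncated at zero.
#'
#' The planted multipliers are calibrated on the observable scale: the
#' deviant-window profile is scaled so that the expectation of the
#' truncated (noisy) window mean equals the multiplier times the
#' expectation of the standard-window mean, using the same 2-frame-offset
#' windows the prediction-error analysis uses.
#'
#' @param cells a `cell_spec` from [generate_population()].
#' @param events an `event_table` from [build_protocol()].
#' @param config the [generator_config()].
#' @param seed optional integer; defaults to a child of `config$seed`.
#' @return a matrix (class `activity_matrix`) of cells x frames nonnegative
#'   amplitudes with attributes `frame_rate`, `cell_meta` (mouse/day/class),
#'   and `ground_truth` (the full `cell_spec`).
#' @export
simulate_session <- function(cells, events, config, seed = NULL) {
  stopifnot(inherits(cells, "cell_spec"), nrow(cells) > 0,
            inherits(events, "event_table"))
  day <- attr(cells, "day")
  if (is.null(seed)) seed <- child_seed(config$seed, "session", day)
  set.seed(as.integer(seed))

  fr <- attr(events, "frame_rate")
  n_frames <- session_frames(events)
  n_cells <- nrow(cells)
  ft <- (seq_len(n_frames) - 1) * 1000 / fr  # frame start times, ms

  A <- matrix(rep(cells$baseline, n_frames), nrow = n_cells)

  # per-cell multiplicative gain random walk over presentations
  pres_ids <- sort(unique(stats::na.omit(events$presentation)))
  n_pres <- length(pres_ids)
  if (n_pres > 0 && config$drift_eta > 0) {
    W <- matrix(stats::rnorm(n_cells * n_pres), nrow = n_cells)
    W <- t(apply(W, 1, cumsum))
    G <- exp(config$drift_eta * W)
  } else {
    G <- matrix(1, nrow = n_cells, ncol = max(n_pres, 1))
  }
  colnames_G <- pres_ids

  el <- events[events$kind == "element", , drop = FALSE]
  gr <- events[events$kind == "gray", , drop = FALSE]
  half_pres <- if (n_pres > 0) pres_ids[ceiling(n_pres / 2)] else 0L

  add_events <- function(idx, ev_rows, profile_fun, profile2_fun = NULL) {
    # ev_rows: event rows sharing a common relative window grid;
    # profile_fun(rel_t) gives per-cell evoked values at window frame times.
    # profile2_fun, when given, replaces it for second-half presentations
    # (latency-swap drift component).
    if (nrow(ev_rows) == 0 || length(idx) == 0) return(invisible())
    w0 <- frames_for_event(ev_rows$onset_ms[1], ev_rows$offset_ms[1], fr, 0L)
    L <- w0$n_frames
    rel_t <- ft[w0$first_frame + seq_len(L)] - ev_rows$onset_ms[1]
    prof <- profile_fun(rel_t)              # n_idx x L
    prof2 <- if (!is.null(profile2_fun)) profile2_fun(rel_t) else prof
    for (j in seq_len(nrow(ev_rows))) {
      wj <- frames_for_event(ev_rows$onset_ms[j], ev_rows$offset_ms[j], fr, 0L)
      cols <- wj$first_frame + seq_len(min(L, wj$n_frames))
      p <- match(ev_rows$presentation[j], colnames_G)
      g <- if (is.na(p)) rep(1, length(idx)) else G[idx, p]
      pr <- if (!is.na(p) && ev_rows$presentation[j] > half_pres) prof2 else prof
      A[idx, cols] <<- A[idx, cols] + pr[, seq_along(cols), drop = FALSE] * g
    }
    invisible()
  }

  bump_profile <- function(rows, rel_t, center_ms) {
    # Gaussian bump sampled at relative frame times, n_rows x length(rel_t)
    rows$amplitude * exp(-outer(center_ms, rel_t, function(c, t) (t - c)^2) /
                           (2 * rows$sigma_ms^2))
  }

  for (letter in c("A", "B", "C", "D")) {
    idx <- which(cells$class == letter)
    if (length(idx) == 0) next
    rows <- cells[idx, , drop = FALSE]
    occ <- el[el$element == letter, , drop = FALSE]
    if (nrow(occ) == 0) next
    for (s in unique(occ$sequence)) {
      for (pos in unique(occ$position[occ$sequence == s])) {
        ev <- occ[occ$sequence == s & occ$position == pos, , drop = FALSE]
        center <- rows$latency_ms  # relative to event onset
        center2 <- ifelse(rows$swap, rows$latency2_ms, rows$latency_ms)
        is_omission <- (letter == "B" && s == "ABBD" && pos == 3)
        is_substitution <- (letter == "C" && s == "ACBD")
        if (!is_omission && !is_substitution) {
          add_events(idx, ev,
                     function(rel_t) bump_profile(rows, rel_t, center),
                     if (any(rows$swap))
                       function(rel_t) bump_profile(rows, rel_t, center2))
        } else {
          # deviant window: same bump shape, rescaled per cell so that the
          # expected truncated analysis-window mean is gain x the standard's
          std_rel_pos <- if (is_omission) 2L else
            which(strsplit("ABCD", "")[[1]] == "C")  # C in ABCD, position 3
          gain <- if (is_omission) rows$omission_gain[1] else
            rows$substitution_gain[1]
          elt_ms <- ev$offset_ms[1] - ev$onset_ms[1]
          # analysis windows relative to presentation start
          dev_rel_on <- (ev$position[1] - 1) * elt_ms
          std_rel_on <- (std_rel_pos - 1) * elt_ms
          dev_af <- pe_window_frames(dev_rel_on, elt_ms, fr) * 1000 / fr - dev_rel_on
          std_af <- pe_window_frames(std_rel_on, elt_ms, fr) * 1000 / fr - std_rel_on
          w0 <- frames_for_event(ev$onset_ms[1], ev$offset_ms[1], fr, 0L)
          rel_t <- ft[w0$first_frame + seq_len(w0$n_frames)] - ev$onset_ms[1]
          prof <- bump_profile(rows, rel_t, center)
          scaled <- prof
          for (ci in seq_along(idx)) {
            b <- rows$baseline[ci]
            std_vals <- rows$amplitude[ci] *
              exp(-(std_af - center[ci])^2 / (2 * rows$sigma_ms[ci]^2))
            target <- gain * mean(truncated_mean(std_vals + b, config$noise_sd))
            dev_shape <- exp(-(dev_af - center[ci])^2 / (2 * rows$sigma_ms[ci]^2))
            k <- calibrate_gain(dev_shape, b, config$noise_sd,
                                target)
            full_shape <- exp(-(rel_t - center[ci])^2 / (2 * rows$sigma_ms[ci]^2))
            scaled[ci, ] <- k * full_shape
          }
          add_events(idx, ev, function(rel_t) scaled)
        }
      }
    }
  }

  # gray-onset cells: bump after gray onset, all sequences
  idx <- which(cells$class == "gray_onset")
  if (length(idx) > 0 && nrow(gr) > 0) {
    rows <- cells[idx, , drop = FALSE]
    add_events(idx, gr, function(rel_t) bump_profile(rows, rel_t, rows$latency_ms))
  }
  # gray-ramp cells: linear rise to gray offset
  idx <- which(cells$class == "gray_ramp")
  if (length(idx) > 0 && nrow(gr) > 0) {
    rows <- cells[idx, , drop = FALSE]
    dur <- gr$offset_ms[1] - gr$onset_ms[1]
    add_events(idx, gr, function(rel_t)
      outer(rows$amplitude, pmax(rel_t, 0) / dur))
  }

  if (config$noise_sd > 0) {
    A <- A + stats::rnorm(length(A), 0, config$noise_sd)
  }
  A[A < 0] <- 0

  meta <- data.frame(mouse = cells$mouse, cell = cells$cell,
                     class = cells$class, day = day,
                     stringsAsFactors = FALSE)
  structure(A, frame_rate = fr, cell_meta = meta, ground_truth = cells,
            day = day, class = c("activity_matrix", "matrix", "array"))
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix> %d cells x %d frames at %g Hz (%s)\n",
              nrow(x), ncol(x), attr(x, "frame_rate"),
              attr(x, "day") %||% "unlabeled"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
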