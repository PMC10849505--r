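# Shared linear-decoder machinery: per-cell standardization using training
# statistics only, then a linear support-vector classifier (cost = 1).

fit_predict_linear <- function(Xtr, ytr, Xte, cost = 1) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  ytr <- factor(ytr)
  if (nlevels(ytr) < 2) stop("need at least 2 classes to decode")
  fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = cost, scale = FALSE)
  as.character(stats::predict(fit, Xte))
}

new_decoder_report <- function(acc, conf_sum, classes, n_iter, chance,
                               extra = list()) {
  conf <- conf_sum / n_iter
  structure(c(list(accuracy = acc,
                   mean_accuracy = mean(acc),
                   sd_accuracy = stats::sd(acc),
                   confusion = conf,
                   classes = classes,
                   n_iter = n_iter,
                   chance = chance), extra),
            class = "decoder_report")
}

#' @export
print.decoder_report <- function(x, ...) {
  cat(sprintf("<decoder_report> %d classes, %d iterations: accuracy %.1f%% +/- %.1f%% (chance %.1f%%)\n",
              length(x$classes), x$n_iter, 100 * x$mean_accuracy,
              100 * (x$sd_accuracy %||% 0), 100 * x$chance))
  invisible(x)
}

row_normalized_confusion <- function(true, pred, classes) {
  cm <- table(factor(true, levels = classes), factor(pred, levels = classes))
  cm <- unclass(cm)
  rs <- rowSums(cm)
  rs[rs == 0] <- 1
  cm / rs
}

shuffle_labels <- function(y, groups, how) {
  if (how == "none") return(y)
  if (how == "global" || is.null(groups)) return(sample(y))
  for (g in unique(groups)) {
    i <- which(groups == g)
    y[i] <- y[i][sample.int(length(i))]
  }
  y
}

#' Stimulus-identity decoding (all element-in-sequence + gray conditions)
#'
#' Trains a linear support-vector classifier on time-averaged population
#' responses over all stimulus conditions. Per iteration each class's
#' trials are split at random into equal train/test halves; accuracies and
#' row-normalized confusion matrices are accumulated. With the standard
#' three-sequence design there are 15 classes (12 element-in-sequence
#' conditions + 3 per-sequence gray conditions) and chance is 1/15.
#'
#' @param X trials x cells response matrix pooled over conditions.
#' @param y class label per trial.
#' @param n_iter repeated random splits.
#' @param seed RNG seed; iteration i uses `seed + i`.
#' @param shuffle `"none"`, or `"global"` to permute labels before training
#'   (empirical chance calibration).
#' @param n_per_class optional subsample size per class (keeps the design
#'   balanced while controlling runtime).
#' @param cost SVM regularization constant.
#' @return a `decoder_report`.
#' @export
decode_stimulus <- function(X, y, n_iter = 100, seed = NULL,
                            shuffle = c("none", "global"),
                            n_per_class = NULL, cost = 1) {
  shuffle <- match.arg(shuffle)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 trials")
  if (!is.null(seed)) set.seed(as.integer(seed))
  acc <- numeric(n_iter)
  conf_sum <- matrix(0, length(classes), length(classes),
                     dimnames = list(classes, classes))
  for (it in seq_len(n_iter)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + it)
    yy <- shuffle_labels(y, NULL, shuffle)
    tr <- unlist(lapply(classes, function(k) {
      i <- which(yy == k)
      if (!is.null(n_per_class) && length(i) > n_per_class) {
        i <- sample(i, n_per_class)
      }
      sample(i, floor(length(i) / 2))
    }))
    te <- if (is.null(n_per_class)) setdiff(seq_along(y), tr) else {
      unlist(lapply(classes, function(k) {
        i <- setdiff(which(yy == k), tr)
        if (length(i) > ceiling(n_per_class / 2)) {
          sample(i, ceiling(n_per_class / 2))
        } else i
      }))
    }
    pred <- fit_predict_linear(X[tr, , drop = FALSE], yy[tr],
                               X[te, , drop = FALSE], cost)
    acc[it] <- mean(pred == yy[te])
    conf_sum <- conf_sum + row_normalized_confusion(yy[te], pred, classes)
  }
  new_decoder_report(acc, conf_sum, classes, n_iter, 1 / length(classes))
}

#' Build the pooled stimulus-condition design for one session
#'
#' Stacks the time-averaged responses of every element-in-sequence
#' condition and per-sequence gray condition (first `offset_frames` frames
#' of each window excluded) into one design matrix with class labels.
#'
#' @inheritParams stimulus_response_sets
#' @return list with `X` (trials x cells), `y` (labels),
#'   `block` (block index per trial).
#' @export
stimulus_condition_matrix <- function(activity, events, offset_frames = 2L) {
  sets <- stimulus_response_sets(activity, events, "context",
                                 include_gray = TRUE,
                                 offset_frames = offset_frames,
                                 mode = "truncate")
  X <- do.call(rbind, lapply(sets, unclass))
  y <- rep(names(sets), vapply(sets, nrow, integer(1)))
  block <- unlist(lapply(sets, function(s) attr(s, "trial_info")$block))
  list(X = X, y = y, block = block)
}

#' Block-identity decoding within one element condition
#'
#' Trains the linear classifier to report which block of the session a
#' trial came from: per iteration, `n_train` randomly chosen trials per
#' block train the decoder and all remaining trials are tested (with the
#' standard 5 blocks x 100 trials this leaves 250 test trials). Optionally
#' normalizes every trial vector to unit length first -- the control that
#' removes global rescaling (photobleaching/adaptation-style) components of
#' drift.
#'
#' @param X trials x cells response matrix for one element condition.
#' @param blocks block index per trial.
#' @param n_train training trials per block.
#' @param n_iter,seed,cost as in [decode_stimulus()].
#' @param shuffle `"none"` or `"global"`.
#' @param normalize scale each trial vector to unit length.
#' @return a `decoder_report` with extra field `n_test` (test trials per
#'   iteration).
#' @export
decode_block <- function(X, blocks, n_train = 50, n_iter = 100, seed = NULL,
                         shuffle = c("none", "global"), normalize = FALSE,
                         cost = 1) {
  shuffle <- match.arg(shuffle)
  blocks <- as.character(blocks)
  classes <- sort(unique(blocks))
  if (length(classes) < 2) stop("need at least 2 blocks")
  sizes <- table(blocks)
  if (any(sizes <= n_train)) stop("every block needs more than n_train trials")
  if (max(sizes) - min(sizes) > 0.1 * max(sizes)) {
    stop("block sizes unequal beyond tolerance")
  }
  if (normalize) {
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm == 0] <- 1
    X <- X / nrm
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  acc <- numeric(n_iter)
  n_test <- integer(n_iter)
  conf_sum <- matrix(0, length(classes), length(classes),
                     dimnames = list(classes, classes))
  for (it in seq_len(n_iter)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + it)
    bb <- shuffle_labels(blocks, NULL, shuffle)
    tr <- unlist(lapply(classes, function(k) sample(which(bb == k), n_train)))
    te <- setdiff(seq_along(bb), tr)
    pred <- fit_predict_linear(X[tr, , drop = FALSE], bb[tr],
                               X[te, , drop = FALSE], cost)
    acc[it] <- mean(pred == bb[te])
    n_test[it] <- length(te)
    conf_sum <- conf_sum + row_normalized_confusion(bb[te], pred, classes)
  }
  new_decoder_report(acc, conf_sum, classes, n_iter, 1 / length(classes),
                     extra = list(n_test = n_test))
}

#' Block decoding pooled over all element conditions
#'
#' Runs [decode_block()] for each element-in-sequence condition of a
#' session and pools accuracies and confusion matrices, reproducing the
#' averaged within-element block decoder.
#'
#' @inheritParams stimulus_response_sets
#' @param n_train,n_iter,seed,normalize,cost passed to [decode_block()].
#' @return a `decoder_report`; extra field `per_condition` holds the
#'   individual reports.
#' @export
block_decoding <- function(activity, events, n_train = 50, n_iter = 100,
                           seed = NULL, normalize = FALSE, cost = 1,
                           offset_frames = 2L) {
  el <- events$kind == "element"
  conds <- unique(events[el, c("sequence", "position")])
  reports <- list()
  for (i in seq_len(nrow(conds))) {
    sel <- el & events$sequence == conds$sequence[i] &
      events$position == conds$position[i]
    rm_ <- time_average(extract_trials(activity, events, sel,
                                       offset_frames, "truncate"))
    blocks <- attr(rm_, "trial_info")$block
    nm <- sprintf("%s.%d", conds$sequence[i], conds$position[i])
    reports[[nm]] <- decode_block(rm_, blocks, n_train, n_iter,
                                  seed = if (is.null(seed)) NULL else seed + 100L * i,
                                  normalize = normalize, cost = cost)
  }
  acc <- rowMeans(vapply(reports, function(r) r$accuracy, numeric(n_iter)))
  conf <- Reduce(`+`, lapply(reports, function(r) r$confusion)) / length(reports)
  classes <- reports[[1]]$classes
  new_decoder_report(acc, conf * n_iter, classes, n_iter, 1 / length(classes),
                     extra = list(per_condition = reports))
}

#' Time-bin decoding within gray periods (or sequence windows)
#'
#' Treats each frame of an aligned window as a class and each window
#' occurrence (e.g. one intersequence gray period) as the sampling unit:
#' per iteration the windows are split at random into equal train/test
#' halves, so all frames of one window land on the same side of the split
#' (no within-trial leakage). At 30 Hz an 800 ms gray period gives 24
#' frame classes and chance 1/24.
#'
#' @param tensor a `trial_tensor` (cells x windows x frames).
#' @param n_iter,seed,cost as in [decode_stimulus()].
#' @param shuffle `"none"`, `"global"`, or `"within_trial"` (permute the
#'   frame labels inside each window -- the leakage detector).
#' @param n_trials optional subsample of windows.
#' @return a `decoder_report` with extra field `accuracy_by_bin` (mean
#'   diagonal of the confusion matrix per time bin).
#' @export
decode_time <- function(tensor, n_iter = 100, seed = NULL,
                        shuffle = c("none", "global", "within_trial"),
                        n_trials = NULL, cost = 1) {
  shuffle <- match.arg(shuffle)
  stopifnot(inherits(tensor, "trial_tensor"))
  d <- dim(tensor)
  n_frames <- d[3]
  if (n_frames < 2) stop("need at least 2 time-bin classes")
  if (!is.null(seed)) set.seed(as.integer(seed))
  trials_all <- seq_len(d[2])
  classes <- sprintf("f%02d", seq_len(n_frames))
  acc <- numeric(n_iter)
  conf_sum <- matrix(0, n_frames, n_frames, dimnames = list(classes, classes))
  for (it in seq_len(n_iter)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + it)
    trials <- if (!is.null(n_trials) && n_trials < d[2]) {
      sample(trials_all, n_trials)
    } else trials_all
    n <- length(trials)
    tr_w <- sample(trials, floor(n / 2))
    te_w <- setdiff(trials, tr_w)
    build <- function(ws) {
      Xl <- lapply(seq_len(n_frames), function(f) t(tensor[, ws, f]))
      X <- do.call(rbind, Xl)
      y <- rep(classes, each = length(ws))
      grp <- rep(ws, times = n_frames)
      list(X = X, y = y, grp = grp)
    }
    tr <- build(tr_w)
    te <- build(te_w)
    how <- if (shuffle == "within_trial") "within" else shuffle
    ytr <- if (shuffle == "none") tr$y else if (shuffle == "global")
      sample(tr$y) else shuffle_labels(tr$y, tr$grp, "within")
    pred <- fit_predict_linear(tr$X, ytr, te$X, cost)
    acc[it] <- mean(pred == te$y)
    conf_sum <- conf_sum + row_normalized_confusion(te$y, pred, classes)
  }
  rep_ <- new_decoder_report(acc, conf_sum, classes, n_iter, 1 / n_frames)
  rep_$accuracy_by_bin <- diag(rep_$confusion)
  rep_
}
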