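test_that("noiseless disjoint-support classes decode perfectly", {
  set.seed(51)
  K <- 4; per <- 12; d <- 8
  X <- do.call(rbind, lapply(seq_len(K), function(k) {
    M <- matrix(0, per, d)
    M[, 2 * k - 1] <- 1 + rnorm(per, 0, 0.01)
    M
  }))
  y <- rep(letters[1:K], each = per)
  r <- decode_stimulus(X, y, n_iter = 5, seed = 2)
  expect_equal(r$mean_accuracy, 1)
  expect_equal(unname(diag(r$confusion)), rep(1, K))
  expect_true(all(abs(rowSums(r$confusion) - 1) < 1e-12))
})

test_that("label shuffling calibrates every decoder to its analytic chance", {
  set.seed(52)
  X <- matrix(abs(rnorm(300 * 12)), ncol = 12)
  y <- rep(letters[1:5], each = 60)
  r <- decode_stimulus(X, y, n_iter = 20, seed = 3, shuffle = "global")
  tol <- max(3 * r$sd_accuracy / sqrt(r$n_iter), 0.02)
  expect_lt(abs(r$mean_accuracy - 0.2), tol + 0.03)
  # block decoder on drift-free data is at chance
  blocks <- rep(1:5, each = 60)
  rb <- decode_block(X, blocks, n_train = 30, n_iter = 10, seed = 4)
  expect_lt(abs(rb$mean_accuracy - 0.2), 0.06)
})

test_that("confusion matrices are row-stochastic", {
  fx <- fx_mixed("day0")
  sc <- stimulus_condition_matrix(fx$activity, fx$events)
  expect_equal(length(unique(sc$y)), 15)
  r <- decode_stimulus(sc$X, sc$y, n_iter = 2, seed = 5, n_per_class = 40)
  expect_true(all(abs(rowSums(r$confusion) - 1) < 1e-9))
  expect_true(all(r$accuracy >= 0 & r$accuracy <= 1))
  expect_gt(r$mean_accuracy, 3 / 15)  # informative population decodes above chance
})

test_that("planted drift makes blocks decodable with distance-ordered errors", {
  pc <- protocol_config(sequences = "ABCD", block_size = 60,
                        blocks_per_sequence = 5, lead_in_ms = 1000,
                        lead_out_ms = 1000, interblock_gap_ms = 1000)
  ev <- build_protocol(pc, "baseline")
  gen <- generator_config(n_mice = 4, cells_per_mouse = 15,
                          class_fractions = list(day0 = c(A = 0.25, B = 0.25,
                                                          C = 0.25, D = 0.25)),
                          drift_eta = 0.03, seed = 19)
  cells <- generate_population(gen, "day0")
  act <- simulate_session(cells, ev, gen)
  sel <- ev$kind == "element" & ev$position == 1
  rm_ <- time_average(extract_trials(act, ev, sel, 2L, "truncate"))
  blocks <- attr(rm_, "trial_info")$block
  r <- decode_block(rm_, blocks, n_train = 30, n_iter = 5, seed = 6)
  expect_gt(r$mean_accuracy, 0.5)
  # confusion mass decays with |true - predicted| block distance
  expect_gt(r$confusion[1, 2], r$confusion[1, 4])
  expect_gt(r$confusion[5, 4], r$confusion[5, 2])
  # the unit-norm control still decodes above chance (drift is not a pure
  # global rescaling once per-cell walks differ)
  rn <- decode_block(rm_, blocks, n_train = 30, n_iter = 5, seed = 6,
                     normalize = TRUE)
  expect_gt(rn$mean_accuracy, 0.3)
})

test_that("time decoding splits by window and detects within-trial leakage", {
  fx <- fx_mixed("day0")
  ev <- fx$events
  tens <- extract_trials(fx$activity, ev, ev$kind == "gray", 0L)
  expect_equal(dim(tens)[3], 24)
  r <- decode_time(tens, n_iter = 3, seed = 7, n_trials = 60)
  expect_gt(r$mean_accuracy, 1 / 24 + 0.02)   # gray-onset + ramp structure
  expect_equal(length(r$accuracy_by_bin), 24)
  # label shuffling within windows (trial structure preserved) -> chance
  rs <- decode_time(tens, n_iter = 3, seed = 7, n_trials = 60,
                    shuffle = "within_trial")
  expect_lt(abs(rs$mean_accuracy - 1 / 24), 0.02)
})

test_that("degenerate decoding designs are rejected", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(decode_stimulus(X, rep("a", 10)), "2 classes")
  expect_error(decode_stimulus(X, c("a", rep(c("a", "b"), c(8, 1)))),
               "at least 2 trials")
  expect_error(decode_block(X, rep(1, 10), n_train = 2), "2 blocks")
  tens1 <- structure(array(rnorm(40), c(2, 20, 1)),
                     class = c("trial_tensor", "array"))
  expect_error(decode_time(tens1), "2 time-bin")
})
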