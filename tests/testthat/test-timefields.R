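test_that("noiseless planted cells are consistent with peaks at their latency", {
  gen <- noiseless_generator("B", n = 20, seed = 23)
  ev <- build_protocol(small_protocol(4, 1), "baseline")
  cells <- generate_population(gen, "day0")
  act <- simulate_session(cells, ev, gen)
  tens <- extract_trials(act, ev, sequence_windows(ev, "ABCD"), 0L)
  tf <- estimate_time_fields(tens)
  expect_true(all(tf$consistent))
  expect_equal(attr(tf, "consistent_fraction"), 1)
  # assigned peak within one frame of the planted latency (B onset 250 ms)
  planted_frame <- floor((250 + cells$latency_ms) * 30 / 1000) + 1
  expect_true(all(abs(tf$peak - planted_frame) <= 1))
})

test_that("pure-noise consistency matches the exact uniform-pair enumeration", {
  # independent frame noise makes each half-average peak uniform on T frames;
  # P(|p_even - p_odd| <= 4) = 196 / 576 for T = 24
  T_ <- 24
  exact <- sum(abs(outer(1:T_, 1:T_, "-")) <= 4) / T_^2
  expect_equal(exact, 196 / 576)
  set.seed(57)
  tens <- array(rnorm(2500 * 8 * T_), dim = c(2500, 8, T_))
  attr(tens, "trial_info") <- data.frame(i = 1:8)
  class(tens) <- c("trial_tensor", "array")
  tf <- estimate_time_fields(tens, tolerance_frames = 4)
  se <- sqrt(exact * (1 - exact) / 2500)
  expect_lt(abs(attr(tf, "consistent_fraction") - exact), 4 * se)
})

test_that("inconsistent and degenerate cells are screened out", {
  # two trials with peaks 10 frames apart
  tens <- array(0, dim = c(2, 2, 24))
  tens[1, 1, 5] <- 1; tens[1, 2, 15] <- 1
  attr(tens, "trial_info") <- data.frame(i = 1:2)
  class(tens) <- c("trial_tensor", "array")
  tf <- estimate_time_fields(tens, tolerance_frames = 4)
  expect_false(tf$consistent[1])
  # all-zero cell is inconsistent by convention
  expect_false(tf$consistent[2])
  expect_true(is.na(tf$peak[2]))
})

test_that("latency histograms conserve consistent cells and sort stably", {
  tens <- array(0, dim = c(6, 4, 24))
  peaks <- c(5, 5, 5, 9, 3, 5)
  for (i in 1:6) tens[i, , peaks[i]] <- 1
  attr(tens, "trial_info") <- data.frame(i = 1:4)
  class(tens) <- c("trial_tensor", "array")
  tf <- estimate_time_fields(tens)
  h <- latency_histogram(tf)
  expect_equal(sum(h$counts, na.rm = TRUE), sum(tf$consistent))
  expect_equal(unname(h$counts[5]), 4L)
  # stable ordering: equal peaks retain input cell order
  expect_equal(h$order, c(5L, 1L, 2L, 3L, 6L, 4L))
  # omitted onset bins drop cells peaking there
  h2 <- latency_histogram(tf, element_onset_frames = c(1, 9),
                          omit_after_onset = 2)
  expect_true(is.na(h2$counts[9]))
  expect_equal(sum(h2$counts, na.rm = TRUE), 5L)
})

test_that("day-0 histograms skew late while day-5 histograms lock to transitions", {
  pc <- small_protocol(30, 1)
  histo_for <- function(day) {
    gen <- generator_config(n_mice = 4, cells_per_mouse = 100,
                            class_fractions = list(day0 = c(B = 1),
                                                   day5 = c(B = 1)),
                            noise_sd = 0.2, seed = 29)
    ev <- build_protocol(pc, "baseline")
    cells <- generate_population(gen, day)
    act <- simulate_session(cells, ev, gen)
    sel <- ev$kind == "element" & ev$sequence == "ABCD" & ev$position == 2
    tens <- extract_trials(act, ev, sel, 0L)
    tf <- estimate_time_fields(tens)
    latency_histogram(tf)$counts
  }
  h0 <- histo_for("day0")
  h5 <- histo_for("day5")
  n <- length(h0)   # 7-frame element window; the ~67 ms information delay
  early <- 1:3      # puts the earliest attainable peaks at frame 3
  mid <- 4:(n - 1)
  late <- (ceiling(n / 2) + 1):n
  # increasing latency density: most day-0 mass in the late half
  expect_gt(sum(h0[late]) / sum(h0), 0.6)
  # day-5 latencies concentrate at onset and offset, hollowing the middle
  expect_gt(sum(h5[early]) / sum(h5), 2 * sum(h0[early]) / sum(h0))
  expect_lt(sum(h5[mid]) / sum(h5), sum(h0[mid]) / sum(h0))
})

test_that("cross-validated ordering sorts on even halves only", {
  set.seed(61)
  tens <- array(abs(rnorm(30 * 10 * 24)), dim = c(30, 10, 24))
  for (i in 1:30) tens[i, , (i %% 20) + 2] <- tens[i, , (i %% 20) + 2] + 5
  attr(tens, "trial_info") <- data.frame(i = 1:10)
  class(tens) <- c("trial_tensor", "array")
  tf <- estimate_time_fields(tens)
  h_even <- latency_histogram(tf, sort_reference = "even")
  expect_equal(h_even$order,
               tf$cell[tf$consistent][order(tf$peak_even[tf$consistent])])
})
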