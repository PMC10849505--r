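test_that("selectivity rule labels a dominant response and rejects ties", {
  M <- matrix(c(10, 1, 1.1, 0.9, 1), nrow = 1,
              dimnames = list(NULL, c("A", "B", "C", "D", "gray")))
  out <- classify_selectivity(M, k_sd = 2, sd_mode = "stimulus_means")
  expect_equal(out$label, "A")
  # all means equal: no margin anywhere
  M2 <- matrix(rep(2, 5), nrow = 1, dimnames = dimnames(M))
  expect_equal(classify_selectivity(M2, sd_mode = "stimulus_means")$label, "none")
  expect_error(classify_selectivity(M[, 1:2, drop = FALSE],
                                    sd_mode = "stimulus_means"), "3 stimuli")
})

test_that("selectivity is invariant to common rescaling and monotone in k_sd", {
  set.seed(21)
  M <- matrix(abs(rnorm(50 * 5, 1, 0.5)), ncol = 5,
              dimnames = list(NULL, c("A", "B", "C", "D", "gray")))
  M[1:10, 2] <- M[1:10, 2] + 4
  l1 <- classify_selectivity(M, sd_mode = "stimulus_means")$label
  l2 <- classify_selectivity(M * 7.3, sd_mode = "stimulus_means")$label
  expect_equal(l1, l2)
  counts <- vapply(c(0.5, 1, 2, 4), function(k)
    sum(classify_selectivity(M, k, "stimulus_means")$label != "none"),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted day-0 selectivity fractions are recovered", {
  fx <- fx_mixed("day0")
  st <- selectivity_table(fx$activity, fx$events)
  planted <- table(fx$cells$class)
  n <- nrow(fx$cells)
  # B fraction within the binomial CI of the planted 10% (the planted count
  # itself is multinomial, so allow both sources of binomial error)
  b_frac <- mean(st$label == "B")
  expect_lt(abs(b_frac - 0.10), 2 * 2 * sqrt(0.1 * 0.9 / n))
  # every element class recovered within a few cells of the planted count
  for (cl in c("A", "B", "C", "D")) {
    expect_lt(abs(sum(st$label == cl) - planted[[cl]]),
              max(3, 0.2 * planted[[cl]]))
  }
  # gray label covers both gray cell subtypes
  expect_lt(abs(sum(st$label == "gray") -
                  (planted[["gray_onset"]] + planted[["gray_ramp"]])), 6)
})

test_that("stimulus-driven flags apply the mean + k*SD threshold", {
  sm <- matrix(c(2.5, 0.4), ncol = 1)
  out <- stimulus_driven_flags(sm, overall_mean = c(1, 1),
                               overall_sd = c(0.5, 0.5))
  expect_true(out$flags[1, 1])     # 2.5 > 1 + 2*0.5
  expect_false(out$flags[2, 1])
  expect_equal(out$driven_fraction, 0.5)
  # silent cell: zero variance, zero response -> no flag
  out0 <- stimulus_driven_flags(matrix(0, 1, 3), 0, 0)
  expect_false(any(out0$flags))
})

test_that("visual modulation separates driven cells and holds its type-I error", {
  # disjoint supports: gratings at 1, gray at 0
  ev <- build_protocol(small_protocol(10, 1), "baseline")
  n <- session_frames(ev)
  A <- matrix(0, nrow = 2, ncol = n)
  el <- ev[ev$kind == "element", ]
  for (i in seq_len(nrow(el))) {
    w <- frames_for_event(el$onset_ms[i], el$offset_ms[i], 30, 0)
    A[1, w$first_frame + seq_len(w$n_frames)] <- 1
  }
  A[2, ] <- rep(c(0.3, 0.7), length.out = n)   # same distribution everywhere
  attr(A, "frame_rate") <- 30
  class(A) <- c("activity_matrix", "matrix", "array")
  vm <- visual_modulation(A, ev)
  expect_true(vm$modulated[1])
  # identical generative distributions reject at about the alpha rate
  set.seed(33)
  B <- matrix(abs(rnorm(400 * n)), nrow = 400)
  attr(B, "frame_rate") <- 30
  class(B) <- c("activity_matrix", "matrix", "array")
  vmB <- visual_modulation(B, ev)
  expect_lt(vmB$modulated_fraction, 0.12)
})

test_that("modulated fraction tracks the planted responsive fraction", {
  fx <- fx_mixed("day0")
  vm <- visual_modulation(fx$activity, fx$events)
  planted_frac <- mean(fx$cells$class != "background")
  expect_lt(abs(vm$modulated_fraction - planted_frac), 0.05)
})

test_that("strict sparseness metric is not more permissive than visual modulation", {
  fx <- fx_mixed("day0")
  st <- selectivity_table(fx$activity, fx$events)
  vm <- visual_modulation(fx$activity, fx$events)
  expect_lte(attr(st, "driven_fraction"), vm$modulated_fraction)
})
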