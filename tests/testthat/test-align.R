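test_that("extract_trials returns one aligned trial per selected event", {
  ev <- fx_small_events()
  A <- matrix(3, nrow = 4, ncol = session_frames(ev))
  attr(A, "frame_rate") <- 30
  class(A) <- c("activity_matrix", "matrix", "array")
  sel <- ev$kind == "element" & ev$sequence == "ABCD" & ev$position == 2
  tens <- extract_trials(A, ev, sel, 2L, "shift")
  expect_equal(dim(tens)[2], sum(sel))
  expect_true(all(tens == 3))
  expect_equal(dim(tens)[3], 7)   # 250 ms window, full length preserved
  trunc <- extract_trials(A, ev, sel, 2L, "truncate")
  expect_equal(dim(trunc)[3], 5)  # 2 frames dropped
  expect_error(extract_trials(A, ev, rep(FALSE, nrow(ev))), "no events")
})

test_that("shift mode starts 2 frames later but keeps the window length", {
  ev <- build_protocol(small_protocol(2, 1), "training")
  n <- session_frames(ev)
  A <- matrix(rep(seq_len(n), each = 1), nrow = 1)  # frame index as value
  attr(A, "frame_rate") <- 30
  class(A) <- c("activity_matrix", "matrix", "array")
  sel <- ev$kind == "element" & ev$position == 2 & ev$trial == 1
  t0 <- extract_trials(A, ev, sel, 0L, "shift")
  t2 <- extract_trials(A, ev, sel, 2L, "shift")
  expect_equal(dim(t0)[3], dim(t2)[3])
  expect_equal(as.numeric(t2[1, 1, ]), as.numeric(t0[1, 1, ]) + 2)
})

test_that("time_average is the unweighted frame mean and is homogeneous", {
  ev <- build_protocol(small_protocol(2, 1), "training")
  n <- session_frames(ev)
  set.seed(4)
  A <- matrix(abs(rnorm(3 * n)), nrow = 3)
  attr(A, "frame_rate") <- 30
  class(A) <- c("activity_matrix", "matrix", "array")
  sel <- ev$kind == "gray"
  tens <- extract_trials(A, ev, sel, 0L)
  rm_ <- time_average(tens)
  expect_equal(rm_[1, 1], mean(tens[1, 1, ]))
  expect_equal(dim(rm_), c(sum(sel), 3))
  # degree-1 homogeneity through the full path
  A2 <- A * 2.5
  attr(A2, "frame_rate") <- 30
  class(A2) <- class(A)
  expect_equal(unclass(time_average(extract_trials(A2, ev, sel, 0L))),
               unclass(rm_) * 2.5)
  # frames [1, 3] -> 2
  toy <- array(c(1, 3), dim = c(1, 1, 2))
  attr(toy, "trial_info") <- data.frame(x = 1)
  class(toy) <- c("trial_tensor", "array")
  expect_equal(as.numeric(time_average(toy)), 2)
})

test_that("trial_average supports all/even/odd/first100 subsets", {
  tens <- array(0, dim = c(2, 4, 3))
  tens[1, , ] <- rep(c(0, 2, 0, 2), 3)   # odd trials 0, even trials 2
  tens[2, , ] <- 5
  attr(tens, "trial_info") <- data.frame(i = 1:4)
  class(tens) <- c("trial_tensor", "array")
  expect_equal(as.numeric(trial_average(tens, "odd")[1, ]), rep(0, 3))
  expect_equal(as.numeric(trial_average(tens, "even")[1, ]), rep(2, 3))
  expect_equal(as.numeric(trial_average(tens, "all")[1, ]), rep(1, 3))
  expect_equal(as.numeric(trial_average(tens, "first100")[2, ]), rep(5, 3))
  expect_error(trial_average(tens, integer(0)), "empty")
})

test_that("element and gray windows account for every presentation frame", {
  ev <- build_protocol(small_protocol(2, 1), "baseline")
  pres <- ev[!is.na(ev$presentation) & ev$presentation == 1, ]
  total <- frames_for_event(min(pres$onset_ms), max(pres$offset_ms), 30, 0)$n_frames
  parts <- vapply(seq_len(nrow(pres)), function(i)
    frames_for_event(pres$onset_ms[i], pres$offset_ms[i], 30, 0)$n_frames,
    numeric(1))
  expect_equal(sum(parts), total)
  expect_equal(total, 54)
})

test_that("noiseless bump window mean matches direct enumeration of samples", {
  gen <- noiseless_generator("A")
  ev <- build_protocol(small_protocol(2, 1), "training")
  cells <- generate_population(gen, "day0")
  act <- simulate_session(cells, ev, gen)
  sel <- ev$kind == "element" & ev$position == 1
  rm_ <- time_average(extract_trials(act, ev, sel, 0L, "shift"))
  # oracle: evaluate the Gaussian at the window frame start times directly
  e1 <- ev[sel, ][1, ]
  w <- frames_for_event(e1$onset_ms, e1$offset_ms, 30, 0)
  tms <- (w$first_frame:(w$last_frame - 1)) * 1000 / 30
  expected <- mean(cells$amplitude[1] *
                     exp(-(tms - (e1$onset_ms + cells$latency_ms[1]))^2 /
                           (2 * cells$sigma_ms[1]^2)))
  expect_equal(as.numeric(rm_[1, 1]), expected, tolerance = 1e-10)
})
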