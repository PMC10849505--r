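test_that("population generation respects forced composition and seed", {
  gen <- generator_config(n_mice = 2, cells_per_mouse = 5,
                          class_fractions = list(day0 = c(B = 1)), seed = 3)
  cells <- generate_population(gen, "day0")
  expect_equal(nrow(cells), 10)
  expect_true(all(cells$class == "B"))
  cells2 <- generate_population(gen, "day0")
  expect_identical(cells, cells2)
  expect_error(generator_config(class_fractions = list(day0 = c(A = 0.7, B = 0.5))),
               "more than 1")
})

test_that("a noiseless cell emits a single bump peaking at its planted latency", {
  gen <- noiseless_generator("A")
  pc <- small_protocol(2, 1)
  ev <- build_protocol(pc, "training")  # ABCD only
  cells <- generate_population(gen, "day0")
  act <- simulate_session(cells, ev, gen)
  expect_true(all(act >= 0))
  # peak value equals the amplitude (bump sampled at/near its center)
  expect_lt(abs(max(act) - cells$amplitude[1]),
            0.05 * cells$amplitude[1])
  # peak frame = frame containing element onset + latency
  a_ev <- ev[ev$kind == "element" & ev$position == 1, ][1, ]
  center <- a_ev$onset_ms + cells$latency_ms[1]
  expect_lte(abs((which.max(act[1, ]) - 1) - floor(center * 30 / 1000)), 1)
  # with no noise and no drift every trial is identical
  tens <- extract_trials(act, ev, ev$kind == "element" & ev$position == 1, 0L)
  expect_equal(tens[, 1, ], tens[, 2, ])
  expect_equal(trial_average(tens, "even"), trial_average(tens, "odd"))
})

test_that("day-0 latencies skew late while day-5 latencies are bimodal", {
  gen <- generator_config(n_mice = 4, cells_per_mouse = 250,
                          class_fractions = list(day0 = c(B = 1),
                                                 day5 = c(B = 1)),
                          seed = 11)
  l0 <- generate_population(gen, "day0")$latency_ms
  l5 <- generate_population(gen, "day5")$latency_ms
  lo <- gen$latency_offset_ms
  mid <- lo + (250 - lo) / 2
  # increasing density over the post-delay window puts most mass late
  expect_gt(mean(l0 > mid), 0.65)
  # bimodal mixture hollows out the middle third relative to day 0
  in_mid3 <- function(x) mean(x > lo + (250 - lo) / 3 & x < lo + 2 * (250 - lo) / 3)
  expect_lt(in_mid3(l5), in_mid3(l0) / 2)
  expect_true(all(l0 >= lo & l0 <= 250))
})

test_that("planted multiplicative drift decorrelates responses with trial distance", {
  pc <- protocol_config(sequences = "ABCD", block_size = 150,
                        blocks_per_sequence = 2, lead_in_ms = 1000,
                        lead_out_ms = 1000, interblock_gap_ms = 1000)
  ev <- build_protocol(pc, "baseline")
  base <- generator_config(n_mice = 4, cells_per_mouse = 10,
                           class_fractions = list(day0 = c(A = 0.3, B = 0.3,
                                                           C = 0.2, D = 0.2)),
                           seed = 13)
  for (eta in c(0, 0.02)) {
    gen <- base
    gen$drift_eta <- eta
    cells <- generate_population(gen, "day0")
    act <- simulate_session(cells, ev, gen)
    sel <- ev$kind == "element" & ev$position == 2
    rm_ <- time_average(extract_trials(act, ev, sel, 2L, "truncate"))
    dc <- drift_curve(rm_, bin_width = 50)
    if (eta == 0) {
      expect_lt(max(dc$mean_r) - min(dc$mean_r), 0.02)  # flat under exchangeability
    } else {
      expect_true(all(diff(dc$mean_r) < 0))             # strictly decreasing
    }
  }
})

test_that("omission multiplier of 1 plants no prediction-error effect", {
  gen <- generator_config(n_mice = 2, cells_per_mouse = 40,
                          class_fractions = list(day0 = c(B = 1)),
                          omission_gain = c(day0 = 1, day5 = 1),
                          seed = 17)
  ev <- build_protocol(small_protocol(25, 2), "baseline")
  cells <- generate_population(gen, "day0")
  act <- simulate_session(cells, ev, gen)
  pe <- pe_analysis(act, ev, "omission")
  expect_lt(abs(attr(pe, "mean_ratio") - 1), 0.05)
})

test_that("activity matrices carry metadata and respect the frame span", {
  fx <- fx_mixed("day0")
  act <- fx$activity
  expect_equal(ncol(act), session_frames(fx$events))
  expect_true(all(act >= 0))
  meta <- attr(act, "cell_meta")
  expect_equal(nrow(meta), nrow(act))
  expect_equal(sort(unique(meta$mouse)), 1:8)
})
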