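# Shared fixtures, built lazily and cached for the whole suite.

.fx <- new.env(parent = emptyenv())

fx_get <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

# reduced protocol: same 1800 ms presentation structure, 2 blocks of 20
# per sequence, frame-aligned lead-in/gaps
small_protocol <- function(block_size = 20, blocks_per_sequence = 2) {
  protocol_config(block_size = block_size,
                  blocks_per_sequence = blocks_per_sequence,
                  lead_in_ms = 1000, lead_out_ms = 1000,
                  interblock_gap_ms = 1000)
}

fx_small_events <- function() {
  fx_get("small_events", function() build_protocol(small_protocol(), "baseline"))
}

# 480-cell population under the default study conditions, 100-trial session
fx_mixed <- function(day = "day0") {
  fx_get(paste0("mixed_", day), function() {
    pc <- small_protocol(50, 2)
    ev <- build_protocol(pc, "baseline")
    gen <- generator_config(seed = 5, cells_per_mouse = 60)
    cells <- generate_population(gen, day)
    list(events = ev, cells = cells,
         activity = simulate_session(cells, ev, gen),
         generator = gen)
  })
}

# full-scale protocol (500 presentations/sequence) with a reduced population
fx_full <- function(day = "day0") {
  fx_get(paste0("full_", day), function() {
    pc <- protocol_config()
    ev <- build_protocol(pc, if (day == "day0") "baseline" else "test")
    gen <- generator_config(seed = 101, cells_per_mouse = 12)
    cells <- generate_population(gen, day)
    list(events = ev, cells = cells,
         activity = simulate_session(cells, ev, gen),
         generator = gen)
  })
}

# noiseless, drift-free single-class generator for exact-value checks
noiseless_generator <- function(class = "B", n = 1, seed = 7, ...) {
  fracs <- stats::setNames(list(1), class)
  generator_config(n_mice = 1, cells_per_mouse = n,
                   class_fractions = list(day0 = unlist(fracs),
                                          day5 = unlist(fracs)),
                   amplitude_sdlog = 0, drift_eta = 0, noise_sd = 0,
                   baseline = 0, seed = seed, ...)
}
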