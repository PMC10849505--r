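#' Run configuration for an end-to-end experiment
#'
#' Bundles the protocol, the generator, the stage toggles and the master
#' seed for a reproducible simulate-and-analyze run. All stochastic stages
#' derive their seeds deterministically from `master_seed`.
#'
#' @param protocol a [protocol_config()].
#' @param generator a [generator_config()]; its seed is overridden by
#'   `master_seed`.
#' @param stages character vector of stages to run, a subset of
#'   `c("selectivity", "pe", "correlations", "drift", "pca", "decode",
#'   "timefields")`.
#' @param master_seed integer master seed.
#' @param decode_iter decoder iterations per design.
#' @param decode_per_class trials per class retained by the stimulus
#'   decoder (`NULL` = all).
#' @param drift_bin_width drift-curve bin width in trials.
#' @return object of class `run_config`.
#' @export
run_config <- function(protocol = protocol_config(),
                       generator = generator_config(),
                       stages = c("selectivity", "pe", "correlations",
                                  "drift", "pca", "decode", "timefields"),
                       master_seed = 1,
                       decode_iter = 20,
                       decode_per_class = NULL,
                       drift_bin_width = 50) {
  known <- c("selectivity", "pe", "correlations", "drift", "pca",
             "decode", "timefields")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  generator$seed <- master_seed
  structure(list(protocol = protocol, generator = generator, stages = stages,
                 master_seed = master_seed, decode_iter = decode_iter,
                 decode_per_class = decode_per_class,
                 drift_bin_width = drift_bin_width),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file with optional top-level sections `protocol`,
#' `generator` and `run` whose entries override the corresponding
#' constructor defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pc <- do.call(protocol_config, y$protocol %||% list())
  gl <- y$generator %||% list()
  for (nm in c("class_fractions", "omission_gain", "substitution_gain")) {
    if (!is.null(gl[[nm]])) gl[[nm]] <- lapply(gl[[nm]], unlist)
    if (nm != "class_fractions" && !is.null(gl[[nm]])) {
      gl[[nm]] <- unlist(gl[[nm]])
    }
  }
  gc_ <- do.call(generator_config, gl)
  do.call(run_config, c(list(protocol = pc, generator = gc_), y$run %||% list()))
}

add_row <- function(df, stage, metric, day, value) {
  rbind(df, data.frame(stage = stage, metric = metric, day = day,
                       value = value, stringsAsFactors = FALSE))
}

#' Run the full simulate-and-analyze pipeline
#'
#' Simulates a baseline (day-0) and test (day-5) session from the
#' configured generator and runs every enabled analysis stage on both.
#' Identical configuration and master seed yield identical reports.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`: list with `summary` (long-format
#'   data.frame of stage metrics), `details` (per-stage objects),
#'   `manifest` (stages run), `seed`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  gen <- config$generator
  days <- c("day0", "day5")
  day_kind <- c(day0 = "baseline", day5 = "test")
  sessions <- list()
  for (d in days) {
    ev <- build_protocol(config$protocol, day_kind[[d]])
    cells <- generate_population(gen, d)
    sessions[[d]] <- list(events = ev,
                          activity = simulate_session(cells, ev, gen))
  }

  summary_df <- data.frame(stage = character(), metric = character(),
                           day = character(), value = numeric(),
                           stringsAsFactors = FALSE)
  details <- list()
  pe_store <- list()

  for (d in days) {
    ev <- sessions[[d]]$events
    act <- sessions[[d]]$activity

    if ("selectivity" %in% config$stages) {
      st <- selectivity_table(act, ev)
      s <- attr(st, "summary")
      for (i in seq_len(nrow(s))) {
        summary_df <- add_row(summary_df, "selectivity",
                              paste0("fraction_", s$stimulus[i]), d,
                              s$fraction[i])
      }
      summary_df <- add_row(summary_df, "selectivity", "driven_fraction", d,
                            attr(st, "driven_fraction"))
      details[[paste0("selectivity_", d)]] <- st
    }

    if ("pe" %in% config$stages) {
      for (des in c("omission", "substitution")) {
        pe <- pe_analysis(act, ev, des)
        pe_store[[paste(des, d, sep = "_")]] <- pe
        summary_df <- add_row(summary_df, "pe", paste0(des, "_mean_ratio"), d,
                              attr(pe, "mean_ratio"))
        summary_df <- add_row(summary_df, "pe", paste0(des, "_n"), d,
                              attr(pe, "n"))
      }
    }

    if ("correlations" %in% config$stages) {
      for (s in unique(stats::na.omit(ev$sequence))) {
        cs <- element_correlations(act, ev, s)
        summary_df <- add_row(summary_df, "correlations",
                              paste0(s, "_n_coefficients"), d,
                              sum(!is.na(cs$r)))
        summary_df <- add_row(summary_df, "correlations",
                              paste0(s, "_mean_r"), d,
                              mean(cs$r, na.rm = TRUE))
        details[[paste0("correlations_", s, "_", d)]] <- cs
      }
    }

    if ("drift" %in% config$stages) {
      sel <- ev$kind == "element" & ev$sequence == ev$sequence[
        which(ev$kind == "element")[1]] & ev$position == 1
      rm_ <- time_average(extract_trials(act, ev, sel, 2L, "truncate"))
      dc <- drift_curve(rm_, config$drift_bin_width)
      slope <- if (nrow(dc) > 1) {
        stats::coef(stats::lm(mean_r ~ I((dist_lo + dist_hi) / 2), dc))[2]
      } else NA_real_
      summary_df <- add_row(summary_df, "drift", "slope_per_trial", d,
                            unname(slope))
      details[[paste0("drift_", d)]] <- dc
    }

    if ("pca" %in% config$stages) {
      traces <- lapply(unique(stats::na.omit(ev$sequence)), function(s) {
        trial_average(extract_trials(act, ev, sequence_windows(ev, s), 0L))
      })
      names(traces) <- unique(stats::na.omit(ev$sequence))
      pd <- pca_untangle(traces)
      summary_df <- add_row(summary_df, "pca", "n_components_90", d,
                            pd$n_components)
      details[[paste0("pca_", d)]] <- pd
    }

    if ("decode" %in% config$stages) {
      sc <- stimulus_condition_matrix(act, ev)
      rep_ <- decode_stimulus(sc$X, sc$y, n_iter = config$decode_iter,
                              seed = config$master_seed + 71L,
                              n_per_class = config$decode_per_class)
      summary_df <- add_row(summary_df, "decode", "stimulus_accuracy", d,
                            rep_$mean_accuracy)
      details[[paste0("decode_stimulus_", d)]] <- rep_
    }

    if ("timefields" %in% config$stages) {
      s1 <- unique(stats::na.omit(ev$sequence))[1]
      tens <- extract_trials(act, ev, sequence_windows(ev, s1), 0L)
      tf <- estimate_time_fields(tens)
      summary_df <- add_row(summary_df, "timefields", "consistent_fraction",
                            d, attr(tf, "consistent_fraction"))
      details[[paste0("timefields_", d)]] <- tf
    }
  }

  if ("pe" %in% config$stages) {
    for (des in c("omission", "substitution")) {
      cmp <- compare_days(pe_store[[paste0(des, "_day0")]],
                          pe_store[[paste0(des, "_day5")]])
      summary_df <- add_row(summary_df, "pe", paste0(des, "_ks_p"), "both",
                            cmp$p.value)
    }
  }

  structure(list(summary = summary_df, details = details,
                 manifest = config$stages, seed = config$master_seed,
                 config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, stages: %s\n", x$seed,
              paste(x$manifest, collapse = ", ")))
  print(utils::head(x$summary, 20))
  if (nrow(x$summary) > 20) cat("...", nrow(x$summary) - 20, "more rows\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly. Writes `summary.csv` and
#'   `summary.json`.
#' @export
write_run_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = report$seed, stages = report$manifest,
                            summary = report$summary),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
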