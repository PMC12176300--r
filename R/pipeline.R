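#' Configuration for the end-to-end analysis pipeline
#'
#' Collects every tunable of the hormone-oscillation analysis in one
#' validated, serializable object. All randomness downstream is governed by
#' the seeds recorded here, so a config fully determines the result bundle.
#'
#' @param hormone Input hormone series: a [hormone_cycle_spec()] (simulate),
#'   a `cycle_cohort`, a list of [cycle_series()], or a path to a tidy CSV
#'   as written by [write_cohort_csv()].
#' @param analyte Analyte to select when reading from CSV.
#' @param oversample,max_period_fraction Spectral settings (see
#'   [build_frequency_grid()]).
#' @param fap FAP method: `"bootstrap"`, `"baluev"` or `"none"`.
#' @param n_resamples Bootstrap resamples (>= 99).
#' @param windows Named cycle-phase windows to map onto each fitted cycle:
#'   a list of [phase_window()] objects (default: the luteal and
#'   late-luteal windows of [luteal_phase_windows()]), or NULL to skip.
#' @param immune Optional immune measurements: an [immune_count_spec()]
#'   (simulate) or a data.frame with columns `animal_id, phase, population,
#'   value`; NULL to skip the fold-change stage.
#' @param reference_phase Reference for fold changes (default `"first"`).
#' @param fdr FDR method for the significance table (`"BH"` or `"BKY"`).
#' @param seed Master seed for the FAP permutation streams.
#' @param out_dir Output directory for CSV/JSON artifacts and the manifest;
#'   NULL (default) returns the bundle without writing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(hormone, analyte = "progesterone",
                            oversample = 5, max_period_fraction = 1,
                            fap = c("bootstrap", "baluev", "none"),
                            n_resamples = 999L,
                            windows = luteal_phase_windows(),
                            immune = NULL, reference_phase = "first",
                            fdr = c("BH", "BKY"), seed = 1L,
                            out_dir = NULL) {
  fap <- match.arg(fap)
  fdr <- match.arg(fdr)
  if (!is.null(windows)) {
    if (inherits(windows, "phase_window")) windows <- list(windows)
    ok <- all(vapply(windows, inherits, logical(1L), "phase_window"))
    if (!ok) stop("'windows' must be phase_window objects")
  }
  structure(
    list(hormone = hormone, analyte = analyte, oversample = oversample,
         max_period_fraction = max_period_fraction, fap = fap,
         n_resamples = as.integer(n_resamples), windows = windows,
         immune = immune, reference_phase = reference_phase, fdr = fdr,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

# Small deterministic content hash (FNV-1a over the serialized object);
# avoids a dependency on a hashing package for provenance stamps.
.config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full oscillation-analysis pipeline
#'
#' Orchestrates the stages end to end: obtain the hormone cohort (simulate
#' or read), fit every animal with [cycle_fit()], summarize the cohort's
#' dominant period (arithmetic mean of per-animal peak periods, with the
#' range), map the configured cycle-phase windows onto each fitted cycle,
#' and — when immune measurements are supplied — compute fold changes and
#' their signed-rank/FDR significance table. Any stage error aborts the run
#' with a stage-labelled message; nothing is written on failure.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `cycle_pipeline` with components `fits` (one
#'   [cycle_fit()] per animal), `cohort` (data.frame of per-animal period,
#'   power, fap), `summary` (mean/min/max dominant period),
#'   `mapped_windows` (per animal, per window day intervals), `fold_changes`
#'   and `fold_tests` (NULL without immune input), and `provenance` (config
#'   hash, seed, timestamps are deliberately excluded so reruns are
#'   byte-identical).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must be a pipeline_config")
  }
  cohort <- .stage("input", {
    h <- config$hormone
    if (inherits(h, "hormone_cycle_spec")) {
      generate_cohort(h)
    } else if (inherits(h, "cycle_cohort")) {
      h
    } else if (is.character(h) && length(h) == 1L) {
      df <- utils::read.csv(h, stringsAsFactors = FALSE)
      ids <- unique(df$animal_id[df$analyte == config$analyte])
      if (length(ids) == 0L) stop("no rows for analyte ", config$analyte)
      lapply(ids, function(id) read_series_csv(h, id, config$analyte))
    } else if (is.list(h) &&
               all(vapply(h, inherits, logical(1L), "cycle_series"))) {
      h
    } else {
      stop("unsupported hormone input")
    }
  })
  fits <- .stage("spectral", {
    lapply(seq_along(cohort), function(i) {
      cycle_fit(cohort[[i]], oversample = config$oversample,
                max_period_fraction = config$max_period_fraction,
                fap = config$fap, n_resamples = config$n_resamples,
                seed = (config$seed + i) %% 2147483647L)
    })
  })
  cohort_tab <- .stage("summary", {
    data.frame(
      animal_id = vapply(fits, function(f) f$series$animal_id, character(1L)),
      period = vapply(fits, function(f) f$peak$period, numeric(1L)),
      power = vapply(fits, function(f) f$peak$power, numeric(1L)),
      fap = vapply(fits, function(f) {
        if (is.null(f$fap)) NA_real_ else f$fap$fap
      }, numeric(1L)),
      stringsAsFactors = FALSE
    )
  })
  summ <- list(
    mean_period = mean(cohort_tab$period),
    min_period = min(cohort_tab$period),
    max_period = max(cohort_tab$period),
    n_animals = nrow(cohort_tab)
  )
  mapped <- if (is.null(config$windows)) NULL else .stage("phase_map", {
    rows <- lapply(fits, function(f) {
      per_win <- lapply(config$windows, function(pw) {
        dw <- phase_to_day_window(f$waveform, pw)
        data.frame(
          animal_id = f$series$animal_id, window = dw$name,
          angle_start = pw$angle_start, angle_end = pw$angle_end,
          day_start = dw$day_start, day_end = dw$day_end,
          cycle_length = dw$cycle_length, stringsAsFactors = FALSE
        )
      })
      do.call(rbind, per_win)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
  folds <- NULL
  tests <- NULL
  if (!is.null(config$immune)) {
    imm <- .stage("immune_input", {
      if (inherits(config$immune, "immune_count_spec")) {
        generate_immune_counts(config$immune)
      } else if (is.data.frame(config$immune)) {
        config$immune
      } else {
        stop("unsupported immune input")
      }
    })
    folds <- .stage("fold_change", {
      fold_change_vs_reference(imm, reference = config$reference_phase)
    })
    tests <- .stage("fold_tests", {
      fold_significance_table(folds, adjust = config$fdr)
    })
  }
  bundle <- structure(
    list(fits = fits, cohort = cohort_tab, summary = summ,
         mapped_windows = mapped, fold_changes = folds, fold_tests = tests,
         provenance = list(config_hash = .config_hash(unclass(config)),
                           seed = config$seed)),
    class = "cycle_pipeline"
  )
  if (!is.null(config$out_dir)) .write_bundle(bundle, config)
  bundle
}

#' @export
print.cycle_pipeline <- function(x, ...) {
  cat(sprintf(
    "<cycle_pipeline> %d animal(s); mean dominant period %.4g d (range %.4g-%.4g)\n",
    x$summary$n_animals, x$summary$mean_period, x$summary$min_period,
    x$summary$max_period
  ))
  if (!is.null(x$fold_tests)) {
    cat(sprintf("  fold-change tests: %d (population, phase) cells\n",
                nrow(x$fold_tests)))
  }
  cat(sprintf("  provenance: config %s, seed %d\n",
              x$provenance$config_hash, x$provenance$seed))
  invisible(x)
}

.write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- character(0)
  wr <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outs <<- c(outs, name)
  }
  wr(bundle$cohort, "cohort_peaks.csv")
  pg <- do.call(rbind, lapply(bundle$fits, function(f) {
    cbind(animal_id = f$series$animal_id, as.data.frame(f$periodogram))
  }))
  wr(pg, "periodograms.csv")
  waves <- do.call(rbind, lapply(bundle$fits, function(f) {
    data.frame(animal_id = f$series$animal_id, A = f$waveform$A,
               B = f$waveform$B, C = f$waveform$C,
               amplitude = f$waveform$amplitude,
               phase_offset = f$waveform$phase_offset,
               period = f$waveform$period, stringsAsFactors = FALSE)
  }))
  wr(waves, "waveforms.csv")
  if (!is.null(bundle$mapped_windows)) wr(bundle$mapped_windows, "mapped_windows.csv")
  if (!is.null(bundle$fold_changes)) {
    wr(as.data.frame(bundle$fold_changes), "fold_changes.csv")
    wr(bundle$fold_tests, "fold_tests.csv")
  }
  manifest <- list(
    package = "cyclewave",
    config_hash = bundle$provenance$config_hash,
    seed = bundle$provenance$seed,
    summary = bundle$summary,
    files = outs
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
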