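#' Pipeline run configuration
#'
#' Bundles every stage's configuration for a seeded end-to-end run:
#' simulate (or read) -> detect -> extract -> evaluate -> analyze. A single
#' global seed fans out deterministically to per-stage child seeds
#' ([child_seed()]), so each stage is independently reproducible.
#'
#' @param out_dir output directory for the result bundle.
#' @param cohort a [cohort_spec()] for synthetic input, or `NULL` when
#'   reading recordings from `gaze_dir`.
#' @param gaze_dir directory with gaze files and a `manifest.csv` (used
#'   when `cohort` is `NULL`).
#' @param detector a [detector_config()].
#' @param trainer a [trainer_config()].
#' @param protocol a [protocol_config()].
#' @param seed global integer seed, recorded in every output artifact.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir, cohort = cohort_spec(), gaze_dir = NULL,
                       detector = detector_config(),
                       trainer = trainer_config(),
                       protocol = protocol_config(), seed = 1) {
  stopifnot(is.null(cohort) || inherits(cohort, "cohort_spec"),
            !is.null(cohort) || !is.null(gaze_dir))
  structure(list(out_dir = out_dir, cohort = cohort, gaze_dir = gaze_dir,
                 detector = detector, trainer = trainer,
                 protocol = protocol, seed = seed),
            class = "run_config")
}

## fingerprint of the scientific configuration (output location excluded,
## so the same analysis in two directories stamps identically)
config_fingerprint <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  fnv1a_hash(jsonlite::toJSON(rapply(cfg, unclass, how = "list"),
                              auto_unbox = TRUE, digits = NA, null = "null"))
}

#' Run the full pipeline
#'
#' Executes simulate (or read) -> detect -> extract -> evaluate -> analyze
#' and writes a result bundle under `config$out_dir`: gaze files and
#' manifest (for synthetic cohorts), `events.csv`, `features.csv`,
#' `result.json` (accuracy curves, per-fold selections, configs and
#' seeds), an `analysis/` directory (selection-frequency table and
#' hierarchical breakdown, for RFE runs) and a plain-text log with
#' per-stage counts. Every artifact carries the configuration fingerprint
#' and global seed. Any stage failure aborts with a stage-named error; an
#' `INCOMPLETE` marker file is present until the run finishes.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory stage outputs:
#'   `recordings`, `events`, `features`, `result`, `analysis`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out, "INCOMPLETE")
  file.create(marker)
  stamp <- sprintf("gazescreen config=%s seed=%s",
                   config_fingerprint(config), format(config$seed))
  log_lines <- character(0)
  log <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log("%s", stamp)

  ## simulate / read
  recordings <- stage("simulate", {
    if (!is.null(config$cohort)) {
      spec <- config$cohort
      spec$seed <- child_seed(config$seed, 1)
      cohort <- generate_cohort(spec)
      write_cohort(cohort, file.path(out, "gaze"))
      cohort$recordings
    } else {
      read_cohort(config$gaze_dir)
    }
  })
  log("simulate: %d subjects (%s)", length(recordings),
      paste(names(table(vapply(recordings, `[[`, "", "label"))),
            table(vapply(recordings, `[[`, "", "label")),
            sep = " = ", collapse = ", "))

  ## detect
  events <- stage("detect", lapply(recordings, detect_events,
                                   cfg = config$detector))
  kinds <- table(unlist(lapply(events, `[[`, "kind")))
  log("detect: %s", paste(names(kinds), kinds, sep = " = ", collapse = ", "))
  stage("detect", write_events(events, file.path(out, "events.csv"), stamp))

  ## extract
  schema <- feature_schema()
  features <- stage("extract", {
    rows <- lapply(events, function(ev) {
      fv <- extract_features(ev, schema)
      cbind(data.frame(subject_id = attr(ev, "subject_id"),
                       label = attr(ev, "label"), stringsAsFactors = FALSE),
            as.data.frame(as.list(unclass(fv)), check.names = FALSE))
    })
    out_df <- do.call(rbind, rows); rownames(out_df) <- NULL; out_df
  })
  log("extract: %d x %d feature matrix", nrow(features), nrow(schema))
  stage("extract", write_features(features, file.path(out, "features.csv"),
                                  stamp))

  ## evaluate
  result <- stage("evaluate", {
    protocol <- config$protocol
    protocol$seed <- child_seed(config$seed, 4)
    x <- as.matrix(features[, schema$id])
    run_protocol(x, features$label, protocol, config$trainer)
  })
  log("evaluate: best accuracy %.1f%% at n = %d",
      max(result$metrics$accuracy_mean), best_n_features(result))
  stage("evaluate", {
    best <- best_n_features(result)
    sel <- if (result$protocol$fs_method == "rfe")
      lapply(result$folds, function(fr)
        result$feature_ids[fr$ranking[seq_len(best)]])
    payload <- list(schema_version = "1.0", stamp = stamp,
                    seed = config$seed,
                    protocol = result$protocol, trainer = result$trainer,
                    positive = result$positive,
                    n_subjects = result$n_subjects,
                    metrics = result$metrics, best_n = best,
                    fold_selected_at_best_n = sel)
    jsonlite::write_json(payload, file.path(out, "result.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
  })

  ## analyze
  analysis <- stage("analyze", {
    if (result$protocol$fs_method != "rfe") {
      log("analyze: skipped (no RFE selections to analyze)")
      NULL
    } else {
      adir <- file.path(out, "analysis")
      dir.create(adir, showWarnings = FALSE)
      freq <- selection_frequencies(result, schema)
      con <- file(file.path(adir, "frequency_table.csv"), "w")
      writeLines(paste0("# ", stamp), con)
      utils::write.csv(data.frame(id = names(freq),
                                  count = as.integer(freq)),
                       con, row.names = FALSE, quote = FALSE)
      close(con)
      thr <- length(result$folds) / 2
      bd <- hierarchical_breakdown(freq, thr, schema)
      jsonlite::write_json(
        list(stamp = stamp, threshold = thr,
             n_selected = bd$n_selected,
             share_selected = bd$share_selected,
             total_frequency = bd$total_frequency,
             class_shares = bd$class_shares,
             spatial = bd$spatial, temporal = bd$temporal),
        file.path(adir, "breakdown.json"),
        auto_unbox = TRUE, digits = NA, force = TRUE)
      log("analyze: %d features above %g folds (%.1f%%)",
          bd$n_selected, thr, bd$share_selected)
      list(frequencies = freq, breakdown = bd)
    }
  })

  writeLines(log_lines, file.path(out, "pipeline_log.txt"))
  jsonlite::write_json(list(stamp = stamp, seed = config$seed,
                            fingerprint = config_fingerprint(config),
                            stages = log_lines),
                       file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  file.remove(marker)
  invisible(list(recordings = recordings, events = events,
                 features = features, result = result,
                 analysis = analysis, paths = out))
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the [run_config()] structure: top-level keys `seed`,
#' `out_dir`, `gaze_dir`, and nested maps `cohort` (fields of
#' [cohort_spec()], with `hr_params`/`lr_params`/`layout` as nested maps),
#' `detector`, `trainer` and `protocol`. Missing fields take the package
#' defaults.
#'
#' @param path YAML file path.
#' @param out_dir override for the output directory.
#' @param seed override for the global seed.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  cohort <- NULL
  if (!is.null(y$cohort)) {
    ca <- y$cohort
    ca$hr_params <- build(hr_gaze_params, ca$hr_params)
    ca$lr_params <- build(lr_gaze_params, ca$lr_params)
    ca$layout <- build(text_layout, ca$layout)
    cohort <- do.call(cohort_spec, ca)
  }
  run_config(out_dir = out_dir %||% y$out_dir %||% ".",
             cohort = cohort, gaze_dir = y$gaze_dir,
             detector = build(detector_config, y$detector),
             trainer = build(trainer_config, y$trainer),
             protocol = build(protocol_config, y$protocol),
             seed = seed %||% y$seed %||% 1)
}
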