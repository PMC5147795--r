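## Canonical 168-feature taxonomy:
##   4 event classes (PF, RF, PS, RS)
##   x { Dur } + { D, M, S, R, A } x { hor, vert } x { version, vergence }
##   x { mean, sd } over the subject's events of that class
## 4 * (1 + 5*2*2) * 2 = 168.

EVENT_CLASSES <- c("PF", "RF", "PS", "RS")
SPATIAL_PARAMS <- c("D", "M", "S", "R", "A")
AXES <- c("hor", "vert")
MODES <- c("version", "vergence")
SUMMARIES <- c("mean", "sd")

#' The fixed 168-feature schema
#'
#' Enumerates the canonical, ordered feature taxonomy: for each event class
#' (PF/RF/PS/RS: progressive/regressive fixation/saccade), the event
#' duration (Dur) plus five spatial parameters -- D (spanning distance,
#' signed), M (mean position), S (standard deviation of position), R
#' (maximum range), A (accumulated distance) -- each measured on the
#' horizontal and vertical axis of the version and vergence signals, and
#' each summarised by its mean and (population) SD over the subject's
#' events of that class. Feature ids follow the pattern
#' `<class>.<param>[.<axis>.<mode>].<summary>`, e.g. `PF.Dur.mean` or
#' `PS.D.hor.version.sd`. The order is: classes PF, RF, PS, RS; within a
#' class Dur first, then parameters D, M, S, R, A nested over axis (hor,
#' vert), mode (version, vergence) and summary (mean, sd).
#'
#' @return a data frame of class `feature_schema` with 168 rows and columns
#'   `id`, `event_class`, `parameter`, `axis`, `mode`, `summary`.
#' @examples
#' nrow(feature_schema())  # 168
#' @export
feature_schema <- function() {
  rows <- list()
  for (cl in EVENT_CLASSES) {
    for (su in SUMMARIES)
      rows[[length(rows) + 1L]] <-
        data.frame(event_class = cl, parameter = "Dur",
                   axis = NA_character_, mode = NA_character_, summary = su,
                   stringsAsFactors = FALSE)
    for (pa in SPATIAL_PARAMS)
      for (ax in AXES)
        for (mo in MODES)
          for (su in SUMMARIES)
            rows[[length(rows) + 1L]] <-
              data.frame(event_class = cl, parameter = pa, axis = ax,
                         mode = mo, summary = su, stringsAsFactors = FALSE)
  }
  sch <- do.call(rbind, rows)
  sch$id <- ifelse(is.na(sch$axis),
                   paste(sch$event_class, sch$parameter, sch$summary,
                         sep = "."),
                   paste(sch$event_class, sch$parameter, sch$axis, sch$mode,
                         sch$summary, sep = "."))
  sch <- sch[, c("id", "event_class", "parameter", "axis", "mode", "summary")]
  class(sch) <- c("feature_schema", "data.frame")
  sch
}

#' Parse a canonical feature id back to its descriptor
#'
#' @param id character vector of feature ids.
#' @return a data frame with columns `event_class`, `parameter`, `axis`,
#'   `mode`, `summary` (axis/mode `NA` for duration features).
#' @export
parse_feature_id <- function(id) {
  parts <- strsplit(id, ".", fixed = TRUE)
  out <- lapply(parts, function(p) {
    if (length(p) == 3L)
      data.frame(event_class = p[1], parameter = p[2], axis = NA_character_,
                 mode = NA_character_, summary = p[3],
                 stringsAsFactors = FALSE)
    else if (length(p) == 5L)
      data.frame(event_class = p[1], parameter = p[2], axis = p[3],
                 mode = p[4], summary = p[5], stringsAsFactors = FALSE)
    else stop("malformed feature id: ", paste(p, collapse = "."))
  })
  do.call(rbind, out)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Low-level parameters of one event
#'
#' Computes the six event parameters: `Dur`, the event duration in ms
#' (last minus first sample time), and for each of the four signals
#' (horizontal/vertical version/vergence) over the event's samples:
#' `D` the signed spanning distance (last minus first position), `M` the
#' mean position, `S` the population SD of position, `R` the maximum range
#' between any two positions, and `A` the accumulated distance over all
#' subsequent positions (path length).
#'
#' @param event a list with `t` (sample times, ms) and `sig` (numeric
#'   matrix with columns `version_x`, `version_y`, `vergence_x`,
#'   `vergence_y`), as returned by [event_signals()].
#' @return a list with scalar `Dur` and a 5 x 4 matrix `spatial` (rows D,
#'   M, S, R, A; columns the four signals).
#' @export
event_parameters <- function(event) {
  t <- event$t; sig <- event$sig
  stopifnot(length(t) >= 1, nrow(sig) == length(t))
  spatial <- apply(sig, 2, function(s) {
    s <- s[!is.na(s)]
    if (length(s) == 0) return(c(D = NA, M = NA, S = NA, R = NA, A = NA))
    c(D = s[length(s)] - s[1],
      M = mean(s),
      S = pop_sd(s),
      R = max(s) - min(s),
      A = sum(abs(diff(s))))
  })
  rownames(spatial) <- SPATIAL_PARAMS
  list(Dur = t[length(t)] - t[1], spatial = spatial)
}

#' Extract the sample series of one event
#'
#' @param events a `gaze_events` object.
#' @param i event row index.
#' @return a list with `t` (times, ms) and `sig` (samples x 4 signal
#'   matrix), suitable for [event_parameters()].
#' @export
event_signals <- function(events, i) {
  sig <- attr(events, "signals")
  idx <- events$start_idx[i]:events$end_idx[i]
  list(t = sig$time_ms[idx],
       sig = cbind(version_x = sig$version_x[idx],
                   version_y = sig$version_y[idx],
                   vergence_x = sig$vergence_x[idx],
                   vergence_y = sig$vergence_y[idx]))
}

## map (axis, mode) to a column of the event signal matrix
signal_column <- function(axis, mode) {
  paste0(mode, "_", c(hor = "x", vert = "y")[axis])
}

#' Extract a subject's 168-feature vector
#'
#' Pools the classified events into the four classes PF/RF/PS/RS
#' (progressive/regressive fixations/saccades; sweeps, transients,
#' distortions and direction-less fixations contribute to no pool). Within
#' each pool every event parameter forms a distribution over events, and
#' the feature value is that distribution's mean or population SD. Empty
#' pools yield zero-filled entries and a per-class flag.
#'
#' @param events a `gaze_events` object with directions assigned.
#' @param schema the [feature_schema()].
#' @return an object of class `feature_vector`: a named numeric vector of
#'   length 168 aligned to the schema, with attributes `subject_id`,
#'   `label` and `empty_class_flags` (named logical, `TRUE` where the event
#'   class had zero events).
#' @export
extract_features <- function(events, schema = feature_schema()) {
  stopifnot(inherits(events, "gaze_events"))
  pools <- list(
    PF = which(events$kind == "fixation" & events$direction == "progressive"),
    RF = which(events$kind == "fixation" & events$direction == "regressive"),
    PS = which(events$kind == "saccade" & events$direction == "progressive"),
    RS = which(events$kind == "saccade" & events$direction == "regressive"))
  ## per-pool event parameter tables: Dur vector + per-event spatial arrays
  pool_params <- lapply(pools, function(idx) {
    lapply(idx, function(i) event_parameters(event_signals(events, i)))
  })
  flags <- vapply(pools, function(idx) length(idx) == 0L, logical(1))
  if (all(flags))
    message("degenerate subject '", attr(events, "subject_id"),
            "': no directional fixations or saccades; all-zero features")

  values <- numeric(nrow(schema))
  for (j in seq_len(nrow(schema))) {
    d <- schema[j, ]
    pp <- pool_params[[d$event_class]]
    if (length(pp) == 0L) { values[j] <- 0; next }
    v <- if (d$parameter == "Dur")
      vapply(pp, `[[`, numeric(1), "Dur")
    else
      vapply(pp, function(p)
        p$spatial[d$parameter, signal_column(d$axis, d$mode)], numeric(1))
    v <- v[!is.na(v)]
    values[j] <- if (length(v) == 0L) 0
    else if (d$summary == "mean") mean(v) else pop_sd(v)
  }
  names(values) <- schema$id
  structure(values, class = "feature_vector",
            subject_id = attr(events, "subject_id"),
            label = attr(events, "label"),
            empty_class_flags = flags)
}

#' @export
print.feature_vector <- function(x, ...) {
  flags <- attr(x, "empty_class_flags")
  cat(sprintf("Feature vector for '%s' (%s): %d features",
              attr(x, "subject_id"), attr(x, "label"), length(x)))
  if (any(flags)) cat("; empty classes:",
                      paste(names(flags)[flags], collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Feature matrix of a cohort
#'
#' Detects events and extracts the 168-feature vector for every recording.
#'
#' @param cohort a `gaze_cohort` (or plain list of `gaze_recording`s).
#' @param cfg a [detector_config()].
#' @param schema the [feature_schema()].
#' @return a data frame: `subject_id`, `label`, then one column per schema
#'   feature.
#' @export
cohort_features <- function(cohort, cfg = detector_config(),
                            schema = feature_schema()) {
  recs <- if (inherits(cohort, "gaze_cohort")) cohort$recordings else cohort
  rows <- lapply(recs, function(rec) {
    fv <- extract_features(detect_events(rec, cfg), schema)
    cbind(data.frame(subject_id = rec$subject_id, label = rec$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(fv)), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
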