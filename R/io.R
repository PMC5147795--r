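## File formats (all UTF-8 delimited text):
##  - gaze file: one header line, columns
##      time_ms, lx_deg, ly_deg, rx_deg, ry_deg, valid_l, valid_r
##    one file per subject; invalid samples keep their row with validity 0
##    and empty position fields. Positions are degrees of visual angle,
##    x rightward, y downward, origin at the start of the first text line.
##  - cohort manifest: filename, subject_id, label
##  - events file: subject_id, kind, direction, start_ms, end_ms,
##    start_idx, end_idx
##  - feature matrix: subject_id, 168 feature columns (canonical ids),
##    label

#' Write / read a single-subject gaze file
#'
#' @param rec a `gaze_recording`.
#' @param path output file path.
#' @return `write_gaze_file()` returns `path` invisibly;
#'   `read_gaze_file()` returns a `gaze_recording`.
#' @export
write_gaze_file <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  utils::write.csv(rec$samples, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_gaze_file
#' @param subject_id,label metadata; the id defaults to the file name.
#' @param sampling_rate Hz; inferred from the time stamps when `NULL`.
#' @export
read_gaze_file <- function(path, subject_id = NULL, label = "unknown",
                           sampling_rate = NULL) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ms", "lx_deg", "ly_deg", "rx_deg", "ry_deg",
            "valid_l", "valid_r")
  if (!all(need %in% names(s)))
    stop("gaze file ", path, " lacks columns: ",
         paste(setdiff(need, names(s)), collapse = ", "))
  if (is.null(sampling_rate))
    sampling_rate <- 1000 / stats::median(diff(s$time_ms))
  structure(list(subject_id = subject_id %||%
                   sub("\\.[^.]*$", "", basename(path)),
                 label = label, sampling_rate = sampling_rate,
                 samples = s[need]),
            class = "gaze_recording")
}

#' Write / read a cohort as gaze files plus a manifest
#'
#' @param cohort a `gaze_cohort` or list of recordings.
#' @param dir output directory (created if needed); one gaze file per
#'   subject plus `manifest.csv` mapping filename to subject id and label.
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns a list of `gaze_recording`s.
#' @export
write_cohort <- function(cohort, dir) {
  recs <- if (inherits(cohort, "gaze_cohort")) cohort$recordings else cohort
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(filename = paste0(
    vapply(recs, `[[`, "", "subject_id"), ".csv"),
    subject_id = vapply(recs, `[[`, "", "subject_id"),
    label = vapply(recs, `[[`, "", "label"),
    stringsAsFactors = FALSE)
  for (i in seq_along(recs))
    write_gaze_file(recs[[i]], file.path(dir, manifest$filename[i]))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    f <- file.path(dir, manifest$filename[i])
    if (!file.exists(f))
      stop("gaze file referenced by manifest is missing: ", f)
    read_gaze_file(f, manifest$subject_id[i], manifest$label[i])
  })
}

#' Write / read an events table
#'
#' @param events a `gaze_events` object or a list of them.
#' @param path file path.
#' @param stamp optional comment line (configuration fingerprint) written
#'   as a leading `#` line and skipped on read.
#' @export
write_events <- function(events, path, stamp = NULL) {
  evl <- if (inherits(events, "gaze_events")) list(events) else events
  tab <- do.call(rbind, lapply(evl, function(ev)
    cbind(data.frame(subject_id = attr(ev, "subject_id"),
                     stringsAsFactors = FALSE),
          as.data.frame(ev)[c("kind", "direction", "start_ms", "end_ms",
                              "start_idx", "end_idx")])))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Write / read a cohort feature matrix
#'
#' Layout: first column `subject_id`, then one column per canonical
#' feature id, final column `label`.
#'
#' @param features data frame from [cohort_features()].
#' @param path file path.
#' @param stamp optional leading comment line.
#' @export
write_features <- function(features, path, stamp = NULL) {
  stopifnot(all(c("subject_id", "label") %in% names(features)))
  ord <- c("subject_id", setdiff(names(features),
                                 c("subject_id", "label")), "label")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  utils::write.csv(features[ord], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @return a data frame with `subject_id`, `label` and the feature
#'   columns.
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                  check.names = FALSE)
}
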