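#' Selection frequency of every feature over the internal training folds
#'
#' Counts, for each feature of the schema, the number of training folds
#' (out of folds x repetitions) in which the feature was among the top-`n`
#' selected by recursive feature elimination.
#'
#' @param result a `protocol_result` produced with `fs_method = "rfe"`.
#' @param schema the [feature_schema()]; its ids must match the feature
#'   ids of the result.
#' @param n subset size at which selection is read off the per-fold
#'   ranking; defaults to [best_n_features()] of the result.
#' @return an integer vector of counts named by feature id, in schema
#'   order (class `selection_frequencies`, with attributes `n` and
#'   `total_folds`).
#' @export
selection_frequencies <- function(result, schema = feature_schema(),
                                  n = NULL) {
  stopifnot(inherits(result, "protocol_result"))
  if (result$protocol$fs_method != "rfe")
    stop("selection frequencies require a result with fs_method = 'rfe'")
  if (!identical(schema$id, result$feature_ids))
    stop("schema does not match the result's feature ids")
  n <- n %||% best_n_features(result)
  stopifnot(n >= 1, n <= length(result$feature_ids))
  counts <- integer(length(result$feature_ids))
  for (fr in result$folds) {
    sel <- fr$ranking[seq_len(n)]
    counts[sel] <- counts[sel] + 1L
  }
  names(counts) <- schema$id
  structure(counts, class = "selection_frequencies", n = n,
            total_folds = length(result$folds))
}

#' @export
print.selection_frequencies <- function(x, ...) {
  cat(sprintf(
    "Selection frequencies at n = %d over %d training folds\n",
    attr(x, "n"), attr(x, "total_folds")))
  print(summary(as.integer(x)))
  invisible(x)
}

#' Five-number summary of selection frequencies by event class
#'
#' Quartiles (linear interpolation between order statistics) of the
#' selection counts, overall and within each event class (PF/RF/PS/RS).
#'
#' @param table a [selection_frequencies()] vector (or any numeric vector
#'   named by schema ids).
#' @param schema the [feature_schema()].
#' @return a data frame with one row per group (`all`, then the four
#'   event classes) and columns `group`, `n_features`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
frequency_summary <- function(table, schema = feature_schema()) {
  stopifnot(length(table) > 0)
  if (!all(names(table) %in% schema$id))
    stop("table names do not match the feature schema")
  cls <- schema$event_class[match(names(table), schema$id)]
  five <- function(v) {
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    data.frame(n_features = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5])
  }
  groups <- c(list(all = as.numeric(table)),
              split(as.numeric(table), factor(cls, levels = EVENT_CLASSES)))
  out <- do.call(rbind, lapply(groups, five))
  cbind(data.frame(group = names(groups), stringsAsFactors = FALSE), out,
        row.names = NULL)
}

#' Hierarchical breakdown of frequently selected features
#'
#' Keeps the features selected in more than `threshold` training folds
#' (strict inequality: "the majority of folds" is `> total/2`) and tallies
#' their accumulated selection frequency down the hierarchy event class ->
#' axis -> binocular mode -> parameter for the spatial features, and event
#' class -> duration for the temporal features (the two cannot be
#' meaningfully nested within each other).
#'
#' @param table a [selection_frequencies()] vector.
#' @param threshold count threshold (features with count > threshold are
#'   kept).
#' @param schema the [feature_schema()].
#' @return a list of class `feature_breakdown`: `spatial` and `temporal`
#'   trees (nested nodes with `name`, `frequency`, `children`),
#'   `n_selected`, `share_selected` (% of the schema), `total_frequency`
#'   (accumulated counts of the kept features), and `class_shares` (per
#'   event class, the share of kept features and of accumulated counts, in
#'   %).
#' @export
hierarchical_breakdown <- function(table, threshold,
                                   schema = feature_schema()) {
  stopifnot(threshold >= 0)
  if (!identical(names(table), schema$id))
    stop("table must be aligned to the feature schema")
  keep <- which(as.numeric(table) > threshold)
  sel <- schema[keep, , drop = FALSE]
  sel$count <- as.numeric(table)[keep]

  make_tree <- function(df, levels_chain) {
    build <- function(d, chain) {
      if (length(chain) == 0L) return(NULL)
      parts <- split(d, d[[chain[1]]], drop = TRUE)
      lapply(parts, function(part) {
        node <- list(name = as.character(part[[chain[1]]][1]),
                     level = chain[1],
                     frequency = sum(part$count),
                     children = build(part, chain[-1]))
        class(node) <- "breakdown_node"
        node
      })
    }
    children <- build(df, levels_chain)
    node <- list(name = "all", level = "root",
                 frequency = sum(df$count), children = children)
    class(node) <- "breakdown_node"
    node
  }
  spatial <- make_tree(sel[sel$parameter != "Dur", , drop = FALSE],
                       c("event_class", "axis", "mode", "parameter"))
  temporal <- make_tree(sel[sel$parameter == "Dur", , drop = FALSE],
                        c("event_class", "parameter"))

  cls <- factor(sel$event_class, levels = EVENT_CLASSES)
  class_shares <- data.frame(
    event_class = EVENT_CLASSES,
    n_features = as.integer(table(cls)),
    share_features = as.numeric(100 * table(cls) / max(nrow(sel), 1)),
    share_counts = as.numeric(
      100 * tapply(sel$count, cls, sum, default = 0) /
        max(sum(sel$count), 1)))

  structure(list(spatial = spatial, temporal = temporal,
                 n_selected = nrow(sel),
                 share_selected = 100 * nrow(sel) / nrow(schema),
                 total_frequency = sum(sel$count),
                 threshold = threshold,
                 class_shares = class_shares),
            class = "feature_breakdown")
}

#' @export
print.feature_breakdown <- function(x, ...) {
  cat(sprintf(
    "Features selected in more than %g training folds: %d of 168 (%.1f%%)\n",
    x$threshold, x$n_selected, x$share_selected))
  cat(sprintf("  accumulated selection frequency: %g\n", x$total_frequency))
  print_node <- function(node, indent) {
    cat(sprintf("%s%s: %g\n", strrep("  ", indent), node$name,
                node$frequency))
    for (ch in node$children) print_node(ch, indent + 1)
  }
  cat("spatial:\n"); print_node(x$spatial, 1)
  cat("temporal:\n"); print_node(x$temporal, 1)
  invisible(x)
}

#' Normalized per-group feature distributions
#'
#' Min-max normalizes each requested feature to [0, 1] over both groups
#' pooled (per-group normalization would destroy between-group contrasts)
#' and returns the five-number summary per group, for box-plot style
#' comparison of HR and LR distributions.
#'
#' @param x feature matrix or data frame (subjects x features, columns
#'   named by feature id).
#' @param labels group label per subject.
#' @param features character vector of feature ids to summarise.
#' @return a data frame with columns `feature`, `group`, `min`, `q1`,
#'   `median`, `q3`, `max`, `constant` (TRUE where the feature was
#'   constant over the pooled groups and all values mapped to 0).
#' @export
normalized_group_distributions <- function(x, labels, features) {
  x <- as.data.frame(x)
  missing <- setdiff(features, colnames(x))
  if (length(missing))
    stop("features not present: ", paste(missing, collapse = ", "))
  stopifnot(nrow(x) == length(labels))
  out <- list()
  for (f in features) {
    v <- as.numeric(x[[f]])
    rng <- range(v)
    constant <- rng[1] == rng[2]
    nv <- if (constant) rep(0, length(v)) else (v - rng[1]) / diff(rng)
    for (g in unique(as.character(labels))) {
      q <- stats::quantile(nv[labels == g], c(0, .25, .5, .75, 1),
                           type = 7, names = FALSE)
      out[[length(out) + 1L]] <-
        data.frame(feature = f, group = g, min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5],
                   constant = constant, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
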