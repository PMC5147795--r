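#' Evaluation protocol configuration
#'
#' Repeated stratified k-fold cross-validation with fold-internal feature
#' selection: the dataset is split into `folds` stratified subsets;
#' feature selection (`fs_method`) and standardization are performed
#' inside every training fold; classifiers are trained on the top `n`
#' features for every `n` in `n_features_grid` and evaluated on the
#' held-out fold; the whole procedure is repeated `repetitions` times with
#' fresh random splits. With `y_randomize = TRUE` the training labels of
#' every fold are permuted ([y_randomize_training()]) to establish the
#' chance-level null, while test labels stay untouched.
#'
#' @param folds number of cross-validation folds (>= 2).
#' @param repetitions number of repetitions (default 100; reduce for quick
#'   runs).
#' @param fs_method `"rfe"`, `"random"` or `"none"` (full feature set).
#' @param n_features_grid integer vector of feature-subset sizes; `NULL`
#'   uses a default grid capped at the number of features.
#' @param y_randomize permute training labels (chance-level null).
#' @param seed integer seed; repetition and fold seeds are derived from it.
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(folds = 10, repetitions = 100,
                            fs_method = c("rfe", "random", "none"),
                            n_features_grid = NULL, y_randomize = FALSE,
                            seed = 1) {
  fs_method <- match.arg(fs_method)
  stopifnot(folds >= 2, repetitions >= 1)
  structure(list(folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 fs_method = fs_method,
                 n_features_grid = n_features_grid,
                 y_randomize = isTRUE(y_randomize),
                 seed = seed),
            class = "protocol_config")
}

## stratified fold assignment: within each class, shuffled indices are
## dealt out cyclically, so every fold's class ratio is within one subject
## of the cohort ratio (uses the current RNG stream)
make_stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Classification metrics with HR as the positive class
#'
#' @param truth,predicted vectors of true and predicted class labels.
#' @param positive label of the positive class (default `"HR"`): the
#'   high-risk group, so sensitivity is the proportion of true high-risk
#'   subjects identified and specificity the proportion of low-risk
#'   subjects excluded.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`
#'   in percent; a metric whose denominator is empty is `NA` (reported as
#'   missing, not zero).
#' @export
classification_metrics <- function(truth, predicted, positive = "HR") {
  stopifnot(length(truth) == length(predicted), length(truth) >= 1)
  truth <- as.character(truth); predicted <- as.character(predicted)
  pos <- truth == positive
  c(accuracy = 100 * mean(truth == predicted),
    sensitivity = if (any(pos)) 100 * mean(predicted[pos] == positive)
                  else NA_real_,
    specificity = if (any(!pos)) 100 * mean(predicted[!pos] != positive)
                  else NA_real_)
}

#' Run the repeated cross-validation protocol
#'
#' For each repetition: draw a stratified fold assignment; for each fold,
#' optionally Y-randomize the training labels, standardize features using
#' training-fold statistics only, run the feature-selection method inside
#' the fold, then for each subset size in the grid train a linear SVM on
#' the top features and predict the untouched test fold. Test predictions
#' are pooled per repetition, and accuracy, sensitivity and specificity
#' are reported as mean and SD over repetitions. Test rows take no part in
#' selection or standardization.
#'
#' @param x numeric feature matrix (subjects x features; columns named).
#' @param y two-level vector of class labels (`HR`/`LR` in the screening
#'   setting; `HR` is the positive class when present).
#' @param protocol a [protocol_config()].
#' @param trainer a [trainer_config()].
#' @return an object of class `protocol_result`: list with `metrics` (data
#'   frame: `n`, mean and SD of the three metrics over repetitions),
#'   `per_repetition` (list of `reps x |grid|` matrices `accuracy`,
#'   `sensitivity`, `specificity`), `folds` (per training fold: repetition,
#'   fold, ranking or selected sets, test indices, truth and per-`n`
#'   predictions), `feature_ids`, `positive`, and the config echo with all
#'   seeds.
#' @export
run_protocol <- function(x, y, protocol = protocol_config(),
                         trainer = trainer_config()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2)
    stop("run_protocol needs exactly two classes (got ",
         paste(levels(y), collapse = ", "), ")")
  if (min(table(y)) < protocol$folds)
    stop("each class needs at least `folds` members for stratified ",
         protocol$folds, "-fold cross-validation")
  stopifnot(nrow(x) == length(y))
  p <- ncol(x)
  grid <- protocol$n_features_grid %||%
    unique(pmin(c(1, 2, 4, 8, 16, 32, 48, 64, 96, 128, 168), p))
  stopifnot(all(grid >= 1), all(grid <= p))
  grid <- as.integer(grid)
  positive <- if ("HR" %in% levels(y)) "HR" else levels(y)[1]

  n_grid <- length(grid)
  met <- c("accuracy", "sensitivity", "specificity")
  per_rep <- lapply(met, function(m)
    matrix(NA_real_, protocol$repetitions, n_grid,
           dimnames = list(NULL, grid)))
  names(per_rep) <- met
  fold_records <- vector("list", protocol$repetitions * protocol$folds)

  for (r in seq_len(protocol$repetitions)) {
    rep_seed <- child_seed(protocol$seed, r)
    fold_of <- with_seed(rep_seed, make_stratified_folds(y, protocol$folds))
    pred_pool <- matrix(NA_character_, nrow(x), n_grid)
    for (f in seq_len(protocol$folds)) {
      fold_seed <- child_seed(rep_seed, f)
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      ytr <- y[train_idx]
      if (protocol$y_randomize)
        ytr <- y_randomize_training(ytr, seed = child_seed(fold_seed, 1))
      sc <- standardize_fit(x[train_idx, , drop = FALSE],
                            trainer$standardize)
      xtr <- standardize_apply(x[train_idx, , drop = FALSE], sc)
      xte <- standardize_apply(x[test_idx, , drop = FALSE], sc)

      ranking <- NULL
      selections <- vector("list", n_grid)
      if (protocol$fs_method == "rfe") {
        ranking <- rfe_rank(xtr, ytr, trainer)
        for (g in seq_len(n_grid))
          selections[[g]] <- ranking[seq_len(grid[g])]
      } else if (protocol$fs_method == "random") {
        for (g in seq_len(n_grid))
          selections[[g]] <- select_random_features(
            grid[g], p, seed = child_seed(fold_seed, 1 + g))
      } else {
        for (g in seq_len(n_grid)) selections[[g]] <- seq_len(p)
      }

      preds <- matrix(NA_character_, length(test_idx), n_grid)
      for (g in seq_len(n_grid)) {
        sel <- selections[[g]]
        fit <- fit_linear_svm(xtr[, sel, drop = FALSE], ytr,
                              trainer$svm_cost)
        preds[, g] <- as.character(
          stats::predict(fit, xte[, sel, drop = FALSE]))
      }
      pred_pool[test_idx, ] <- preds
      fold_records[[(r - 1) * protocol$folds + f]] <-
        list(repetition = r, fold = f, seed = fold_seed,
             ranking = ranking,
             selected = if (protocol$fs_method == "random") selections,
             test_idx = test_idx, truth = as.character(y[test_idx]),
             predictions = preds)
    }
    for (g in seq_len(n_grid)) {
      m <- classification_metrics(as.character(y), pred_pool[, g], positive)
      for (mm in met) per_rep[[mm]][r, g] <- m[[mm]]
    }
  }

  metrics <- data.frame(n = grid)
  for (mm in met) {
    metrics[[paste0(mm, "_mean")]] <- colMeans(per_rep[[mm]])
    metrics[[paste0(mm, "_sd")]] <- apply(per_rep[[mm]], 2, stats::sd)
  }
  structure(list(metrics = metrics, per_repetition = per_rep,
                 folds = fold_records, n_features_grid = grid,
                 feature_ids = colnames(x), positive = positive,
                 protocol = utils::modifyList(unclass(protocol),
                                              list(n_features_grid = grid)),
                 trainer = unclass(trainer),
                 n_subjects = nrow(x), class_counts = table(y)),
            class = "protocol_result")
}

#' Best-performing subset size of a protocol run
#'
#' @param result a `protocol_result`.
#' @return the `n` of the grid with the highest mean accuracy (smallest
#'   `n` on ties).
#' @export
best_n_features <- function(result) {
  stopifnot(inherits(result, "protocol_result"))
  result$metrics$n[which.max(result$metrics$accuracy_mean)]
}

#' @export
print.protocol_result <- function(x, ...) {
  b <- which.max(x$metrics$accuracy_mean)
  cat(sprintf(
    "Repeated CV protocol: %d x %d-fold, feature selection '%s'%s\n",
    x$protocol$repetitions, x$protocol$folds, x$protocol$fs_method,
    if (x$protocol$y_randomize) " (Y-randomized)" else ""))
  cat(sprintf("  %d subjects (%s); positive class %s\n", x$n_subjects,
              paste(names(x$class_counts), x$class_counts, sep = " = ",
                    collapse = ", "), x$positive))
  cat(sprintf(
    "  best accuracy %.1f%% +/- %.1f%% at n = %d features\n",
    x$metrics$accuracy_mean[b], x$metrics$accuracy_sd[b], x$metrics$n[b]))
  invisible(x)
}

#' @export
summary.protocol_result <- function(object, ...) {
  print(object)
  cat("\n")
  m <- object$metrics
  m[-1] <- round(m[-1], 1)
  print(m, row.names = FALSE)
  invisible(object$metrics)
}

#' Accuracy curve of a protocol run
#'
#' Mean prediction accuracy against the number of features selected during
#' training, with a band of one standard deviation over repetitions.
#'
#' @param x a `protocol_result`.
#' @param add add to an existing plot.
#' @param col line colour.
#' @param ... passed to [graphics::plot()].
#' @export
plot.protocol_result <- function(x, add = FALSE, col = "steelblue", ...) {
  m <- x$metrics
  if (!add) {
    graphics::plot(m$n, m$accuracy_mean, type = "n", ylim = c(30, 100),
                   xlab = "number of selected features",
                   ylab = "accuracy (%)", ...)
    graphics::abline(h = 50, lty = 3, col = "grey60")
  }
  band <- grDevices::adjustcolor(col, alpha.f = 0.2)
  graphics::polygon(c(m$n, rev(m$n)),
                    c(m$accuracy_mean - m$accuracy_sd,
                      rev(m$accuracy_mean + m$accuracy_sd)),
                    col = band, border = NA)
  graphics::lines(m$n, m$accuracy_mean, col = col, lwd = 2)
  invisible(x)
}

#' Variance-corrected resampled t-test
#'
#' Paired comparison of two classifiers over k overlapping resamples
#' (repeated cross-validation), using the variance correction that
#' accounts for the dependence between resamples through the train/test
#' overlap: `t = mean(d) / sqrt((1/k + rho) * var(d))` with
#' `rho = test_fraction / (1 - test_fraction)` and `k - 1` degrees of
#' freedom. For k-fold cross-validation `test_fraction = 1/folds`. The
#' correction only inflates the variance term, so `|t|` never exceeds the
#' standard paired t statistic.
#'
#' @param d numeric vector of paired score differences over resamples
#'   (k >= 2).
#' @param test_fraction fraction of the data in the test split, in (0, 1).
#' @return a list of class `htest` with `statistic` (t), `parameter` (df)
#'   and `p.value` (two-sided); if the differences have zero variance but
#'   nonzero mean the statistic is infinite with p = 0 and a
#'   `degenerate` flag is set.
#' @export
corrected_resampled_ttest <- function(d, test_fraction) {
  stopifnot(length(d) >= 2, test_fraction > 0, test_fraction < 1,
            all(is.finite(d)))
  k <- length(d)
  v <- stats::var(d)
  m <- mean(d)
  degenerate <- FALSE
  if (v == 0) {
    if (m == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(m) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t_stat <- m / sqrt((1 / k + test_fraction / (1 - test_fraction)) * v)
    p <- 2 * stats::pt(-abs(t_stat), df = k - 1)
  }
  structure(list(statistic = c(t = t_stat), parameter = c(df = k - 1),
                 p.value = p, estimate = c(`mean difference` = m),
                 method = "Variance-corrected resampled t-test",
                 alternative = "two.sided",
                 data.name = deparse(substitute(d)),
                 degenerate = degenerate),
            class = "htest")
}
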