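#' Trainer configuration
#'
#' Settings of the linear support-vector classifier used throughout:
#' soft-margin cost `C` (SMO-style default 1) and whether features are
#' z-scored with training-fold statistics before fitting (required for
#' weight-magnitude feature ranking to be scale-invariant).
#'
#' @param svm_cost positive soft-margin cost.
#' @param standardize z-score features using training statistics.
#' @param seed optional seed stored for bookkeeping.
#' @return an object of class `trainer_config`.
#' @export
trainer_config <- function(svm_cost = 1.0, standardize = TRUE, seed = NULL) {
  stopifnot(svm_cost > 0)
  structure(list(svm_cost = svm_cost, standardize = isTRUE(standardize),
                 seed = seed),
            class = "trainer_config")
}

fit_linear_svm <- function(x, y, cost = 1.0) {
  e1071::svm(x, y, type = "C-classification", kernel = "linear",
             cost = cost, scale = FALSE, fitted = FALSE)
}

## primal weight vector of a fitted linear SVM, aligned to columns of x
linear_svm_weights <- function(model) {
  drop(crossprod(model$coefs, model$SV))
}

#' Rank features by recursive elimination under a linear SVM
#'
#' SVM-RFE: starting from the full feature set, fit a linear SVM, rank the
#' surviving features by the square of their primal weights, remove the
#' single lowest-weight feature, and refit -- one feature at a time until
#' all are exhausted. The returned ranking is the reverse elimination
#' order (best first). Exact ties in squared weight are broken by removing
#' the feature with the larger column index, so the ranking is
#' deterministic.
#'
#' @param x numeric feature matrix (rows subjects; assumed already
#'   standardized if desired).
#' @param y two-level factor of class labels, at least 2 subjects per
#'   class.
#' @param trainer a [trainer_config()].
#' @return integer vector of column indices of `x`, best-ranked first.
#' @export
rfe_rank <- function(x, y, trainer = trainer_config()) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2 || min(table(y)) < 2)
    stop("rfe_rank needs two classes with at least 2 subjects each ",
         "(got ", paste(levels(y), table(y), collapse = ", "), ")")
  p <- ncol(x)
  stopifnot(p >= 1)
  surviving <- seq_len(p)
  elim <- integer(0)
  while (length(surviving) > 1L) {
    fit <- fit_linear_svm(x[, surviving, drop = FALSE], y, trainer$svm_cost)
    w2 <- linear_svm_weights(fit)^2
    tol <- max(w2) * 1e-10
    worst <- max(which(w2 <= min(w2) + tol))
    elim <- c(elim, surviving[worst])
    surviving <- surviving[-worst]
  }
  rev(c(elim, surviving))
}

#' Draw a random feature subset
#'
#' Uniform sample of `n` features without replacement, as used by the
#' random-selection baseline inside each training fold.
#'
#' @param n subset size.
#' @param schema the [feature_schema()] (or an integer giving the number of
#'   features).
#' @param seed optional integer seed.
#' @return integer vector of feature indices (named by feature id when a
#'   schema is given).
#' @export
select_random_features <- function(n, schema = feature_schema(),
                                   seed = NULL) {
  p <- if (is.numeric(schema)) as.integer(schema) else nrow(schema)
  if (n < 1 || n > p) stop("n must be in [1, ", p, "]")
  idx <- with_seed(seed, sample.int(p, n))
  if (!is.numeric(schema)) names(idx) <- schema$id[idx]
  idx
}

#' Y-randomize training labels
#'
#' Chance-level null construction: half of the subjects in each class
#' (floor(n/2) of each, drawn at random) swap class labels, obscuring the
#' true class-feature relationship while approximately preserving class
#' totals. Applied to training folds only; test labels are never touched.
#'
#' @param labels two-level factor or character vector.
#' @param seed optional integer seed.
#' @return labels with the selected entries flipped (same type as input).
#' @export
y_randomize_training <- function(labels, seed = NULL) {
  f <- droplevels(as.factor(labels))
  if (nlevels(f) != 2 || min(table(f)) < 2)
    stop("y_randomize_training needs two classes with at least 2 members")
  lv <- levels(f)
  out <- as.character(f)
  with_seed(seed, {
    for (k in 1:2) {
      idx <- which(f == lv[k])
      flip <- sample(idx, floor(length(idx) / 2))
      out[flip] <- lv[3 - k]
    }
  })
  if (is.factor(labels)) factor(out, levels = lv) else out
}

#' Fit the screening classifier on a full dataset
#'
#' The deployable model: standardizes the feature matrix, ranks all
#' features by recursive elimination ([rfe_rank()]) and fits a linear SVM
#' on the top `n_features`. For honest performance estimates use
#' [run_protocol()], which repeats the selection inside every training
#' fold; this function is the final model one would deploy.
#'
#' @param x numeric feature matrix (subjects x features, columns named).
#' @param y two-level factor of class labels (HR is treated as the
#'   positive class when present).
#' @param n_features number of top-ranked features to keep.
#' @param trainer a [trainer_config()].
#' @return an object of class `screen_svm` with `print`, `summary`,
#'   `coef` and `predict` methods.
#' @export
screen_svm <- function(x, y, n_features = 48, trainer = trainer_config()) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  stopifnot(n_features >= 1, n_features <= ncol(x))
  sc <- standardize_fit(x, trainer$standardize)
  xs <- standardize_apply(x, sc)
  ranking <- rfe_rank(xs, y, trainer)
  sel <- ranking[seq_len(n_features)]
  fit <- fit_linear_svm(xs[, sel, drop = FALSE], y, trainer$svm_cost)
  structure(list(model = fit, selected = sel,
                 feature_ids = colnames(x), ranking = ranking,
                 scaling = sc, levels = levels(y),
                 n_features = n_features, trainer = trainer),
            class = "screen_svm")
}

standardize_fit <- function(x, standardize = TRUE) {
  if (!standardize)
    return(list(center = rep(0, ncol(x)), scale = rep(1, ncol(x))))
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- Inf  # constant features map to 0
  list(center = mu, scale = s)
}

standardize_apply <- function(x, sc) {
  out <- sweep(sweep(as.matrix(x), 2, sc$center, "-"), 2, sc$scale, "/")
  out[!is.finite(out)] <- 0
  out
}

#' @export
print.screen_svm <- function(x, ...) {
  cat(sprintf("Linear SVM screening classifier (%s vs %s)\n",
              x$levels[1], x$levels[2]))
  cat(sprintf("  %d of %d features kept by recursive elimination; C = %g\n",
              x$n_features, length(x$feature_ids), x$trainer$svm_cost))
  invisible(x)
}

#' @export
summary.screen_svm <- function(object, ...) {
  print(object)
  w <- coef(object)
  top <- utils::head(w[order(-abs(w))], 10)
  cat("  top features by |weight|:\n")
  for (i in seq_along(top))
    cat(sprintf("    %-28s %+.3f\n", names(top)[i], top[i]))
  invisible(w)
}

#' @export
coef.screen_svm <- function(object, ...) {
  w <- linear_svm_weights(object$model)
  names(w) <- object$feature_ids[object$selected]
  w
}

#' @export
predict.screen_svm <- function(object, newdata, ...) {
  xs <- standardize_apply(as.matrix(newdata), object$scaling)
  stats::predict(object$model, xs[, object$selected, drop = FALSE])
}
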