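## a minimal hand-built protocol result: 2 repetitions x 2 folds of RFE
## rankings over the 168-feature schema
fake_rfe_result <- function(rankings, n_grid = c(2, 4)) {
  sch <- feature_schema()
  folds <- lapply(seq_along(rankings), function(i)
    list(repetition = (i - 1) %/% 2 + 1, fold = (i - 1) %% 2 + 1,
         ranking = rankings[[i]], test_idx = integer(0),
         truth = character(0), predictions = NULL))
  structure(list(metrics = data.frame(n = n_grid,
                                      accuracy_mean = c(60, 80)),
                 folds = folds, n_features_grid = n_grid,
                 feature_ids = sch$id, positive = "HR",
                 protocol = list(fs_method = "rfe", folds = 2,
                                 repetitions = 2),
                 trainer = list()),
            class = "protocol_result")
}

test_that("selection frequencies count hand-written fold selections", {
  ## rankings: feature 1 always first; feature 2 in three folds' top-4;
  ## feature 5 in one
  base <- 1:168
  r1 <- c(1, 2, 3, 4, setdiff(base, 1:4))
  r2 <- c(1, 2, 4, 3, setdiff(base, 1:4))
  r3 <- c(1, 3, 2, 4, setdiff(base, 1:4))
  r4 <- c(1, 5, 4, 3, setdiff(base, c(1, 3, 4, 5)))
  res <- fake_rfe_result(list(r1, r2, r3, r4))
  freq <- selection_frequencies(res, n = 4)
  expect_identical(unname(freq[1]), 4L)
  expect_identical(unname(freq[2]), 3L)
  expect_identical(unname(freq[5]), 1L)
  expect_identical(sum(freq), 16L)  # 4 folds x 4 selected
  ## defaults to the best-accuracy n (here 4)
  expect_identical(as.integer(selection_frequencies(res)),
                   as.integer(freq))
  ## bounded by the number of folds
  expect_true(all(freq >= 0 & freq <= length(res$folds)))
})

test_that("selection frequencies demand RFE results and a matched schema", {
  res <- fake_rfe_result(list(1:168, 1:168, 1:168, 1:168))
  res$protocol$fs_method <- "random"
  expect_error(selection_frequencies(res), "rfe")
  res$protocol$fs_method <- "rfe"
  bad <- feature_schema()[c(2:168, 1), ]
  expect_error(selection_frequencies(res, schema = bad), "match")
})

test_that("frequency summaries use linear-interpolation quartiles", {
  sch <- feature_schema()
  tab <- stats::setNames(rep(7, 10), sch$id[1:10])
  s <- frequency_summary(tab, sch)
  all_row <- s[s$group == "all", ]
  expect_equal(unlist(all_row[c("min", "q1", "median", "q3", "max")],
                      use.names = FALSE), rep(7, 5))

  tab2 <- stats::setNames(c(0, 2, 35, 660, 1000), sch$id[1:5])
  s2 <- frequency_summary(tab2, sch)
  a <- s2[s2$group == "all", ]
  expect_equal(a$min, 0); expect_equal(a$median, 35)
  expect_equal(a$max, 1000)
  expect_equal(a$q1, 2); expect_equal(a$q3, 660)

  ## grouping covers every feature exactly once
  counts <- stats::setNames(seq_len(168), sch$id)
  s3 <- frequency_summary(counts, sch)
  expect_equal(sum(s3$n_features[s3$group != "all"]), 168)
})

test_that("the hierarchical breakdown conserves frequencies at every level", {
  sch <- feature_schema()
  set.seed(21)
  counts <- stats::setNames(sample(0:1000, 168, replace = TRUE), sch$id)
  bd <- hierarchical_breakdown(counts, threshold = 500, schema = sch)
  node_sum_ok <- function(node) {
    if (length(node$children) == 0) return(TRUE)
    kids <- sum(vapply(node$children, `[[`, numeric(1), "frequency"))
    isTRUE(all.equal(node$frequency, kids)) &&
      all(vapply(node$children, node_sum_ok, logical(1)))
  }
  expect_true(node_sum_ok(bd$spatial))
  expect_true(node_sum_ok(bd$temporal))
  expect_equal(bd$spatial$frequency + bd$temporal$frequency,
               bd$total_frequency)
  expect_equal(bd$n_selected, sum(counts > 500))

  ## threshold at the maximum: empty tree
  bd0 <- hierarchical_breakdown(counts, threshold = max(counts),
                                schema = sch)
  expect_identical(bd0$n_selected, 0L)
  expect_equal(bd0$spatial$frequency, 0)
})

test_that("46 of 168 retained features is a 27.4% share", {
  sch <- feature_schema()
  counts <- stats::setNames(rep(0L, 168), sch$id)
  counts[1:46] <- 800L
  bd <- hierarchical_breakdown(counts, threshold = 500, schema = sch)
  expect_identical(bd$n_selected, 46L)
  expect_equal(round(bd$share_selected, 1), 27.4)
  ## class shares reported both as share of features and of counts
  expect_equal(sum(bd$class_shares$share_features), 100)
  expect_equal(sum(bd$class_shares$share_counts), 100)
})

test_that("normalized distributions span [0,1], preserve order, flag constants", {
  x <- data.frame(a = c(1, 3, 5, 7), b = c(2, 2, 2, 2),
                  check.names = FALSE)
  labels <- c("HR", "HR", "LR", "LR")
  nd <- normalized_group_distributions(x, labels, c("a", "b"))
  a <- nd[nd$feature == "a", ]
  expect_equal(min(a$min), 0); expect_equal(max(a$max), 1)
  ## HR values all below LR: HR median < LR median after normalization
  expect_lt(a$median[a$group == "HR"], a$median[a$group == "LR"])
  b <- nd[nd$feature == "b", ]
  expect_true(all(b$constant))
  expect_true(all(b[, c("min", "median", "max")] == 0))
  expect_error(normalized_group_distributions(x, labels, "zz"),
               "not present")
})

test_that("min-max normalization is idempotent", {
  v <- c(0.1, 0.5, 0.2, 0.9)
  x1 <- data.frame(f = v)
  n1 <- normalized_group_distributions(x1, rep(c("HR", "LR"), 2), "f")
  x2 <- data.frame(f = (v - min(v)) / diff(range(v)))
  n2 <- normalized_group_distributions(x2, rep(c("HR", "LR"), 2), "f")
  expect_equal(n1[, c("min", "q1", "median", "q3", "max")],
               n2[, c("min", "q1", "median", "q3", "max")])
})

test_that("HR fixation durations dominate LR in a strong synthetic cohort", {
  X <- small_cohort_features()
  nd <- normalized_group_distributions(X, X$label, "PF.Dur.mean")
  expect_gt(nd$median[nd$group == "HR"], nd$median[nd$group == "LR"])
})
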