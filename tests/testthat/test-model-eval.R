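test_that("RFE base cases: single feature and deterministic tie-break", {
  d <- gaussian_features(10, 10, 1, 1, 2, seed = 1)
  expect_identical(rfe_rank(d$x, d$y), 1L)
  ## four identical columns: exact weight ties resolved by removing the
  ## larger index first, so the ranking is the schema order
  set.seed(2)
  base <- rnorm(20)
  x <- cbind(f1 = base, f2 = base, f3 = base, f4 = base)
  y <- factor(rep(c("HR", "LR"), 10))
  expect_identical(rfe_rank(x, y), 1:4)
})

test_that("RFE eliminates pure-noise features before separating ones", {
  ## 2 perfectly separating + 2 noise features; cross-check the first
  ## elimination against an independently fitted SVM (kernlab)
  d <- gaussian_features(15, 15, 4, informative = c(1, 2), delta = 4,
                         seed = 3)
  r <- rfe_rank(scale(d$x), d$y)
  expect_setequal(r[1:2], c(1L, 2L))

  kfit <- kernlab::ksvm(scale(d$x), d$y, kernel = "vanilladot",
                        C = 1, scaled = FALSE, kpar = list())
  w_k <- colSums(kernlab::coef(kfit)[[1]] *
                   scale(d$x)[kernlab::SVindex(kfit), , drop = FALSE])
  expect_true(which.min(w_k^2) %in% c(3L, 4L))
})

test_that("degenerate class composition is rejected with a clear error", {
  x <- matrix(rnorm(12), 6, 2)
  expect_error(rfe_rank(x, factor(c("HR", rep("LR", 5)))), "at least 2")
  expect_error(rfe_rank(x, factor(rep("HR", 6))), "two classes")
})

test_that("random feature selection is uniform, seeded and bounded", {
  sch <- feature_schema()
  expect_identical(sort(unname(select_random_features(168, sch, seed = 1))),
                   1:168)
  expect_identical(select_random_features(10, sch, seed = 5),
                   select_random_features(10, sch, seed = 5))
  expect_error(select_random_features(0, sch), "in \\[1")
  expect_error(select_random_features(169, sch), "in \\[1")
  ## uniformity: 1e5 single draws, chi-square GoF not rejected at 0.01
  draws <- vapply(1:100000, function(i)
    select_random_features(1, 168, seed = i)[[1]], numeric(1))
  p <- stats::chisq.test(tabulate(draws, 168))$p.value
  expect_gt(p, 0.01)
})

test_that("Y-randomization flips half of each class and never the rest", {
  y <- factor(rep(c("HR", "LR"), each = 10))
  yr <- y_randomize_training(y, seed = 4)
  expect_identical(sum(yr != y), 10L)  # floor(10/2) per class
  expect_identical(as.integer(table(yr)), as.integer(table(y)))  # totals
  expect_identical(y_randomize_training(y, seed = 4),
                   yr)
  expect_error(y_randomize_training(factor(c("HR", "LR", "LR"))),
               "at least 2")
})

test_that("classification metrics match hand-computed confusion counts", {
  expect_equal(unname(classification_metrics(c("HR", "LR"), c("HR", "LR"))),
               c(100, 100, 100))
  ## TP=3, FN=1, TN=2, FP=2
  truth <- c(rep("HR", 4), rep("LR", 4))
  pred <- c("HR", "HR", "HR", "LR", "HR", "HR", "LR", "LR")
  m <- classification_metrics(truth, pred)
  expect_equal(unname(m), c(62.5, 75, 50))
  ## one-class truth: specificity is missing, not zero
  m2 <- classification_metrics(rep("HR", 3), rep("HR", 3))
  expect_true(is.na(m2["specificity"]))
  expect_equal(unname(m2["sensitivity"]), 100)
})

test_that("corrected resampled t-test matches its closed form", {
  d <- rep(c(1, 2), 5)
  ht <- corrected_resampled_ttest(d, test_fraction = 0.1)
  ## hand evaluation: mean 1.5, var 5/18; denom sqrt((1/10 + 1/9) * 5/18)
  t_hand <- 1.5 / sqrt((1 / 10 + 1 / 9) * stats::var(d))
  expect_equal(unname(ht$statistic), t_hand)
  expect_equal(unname(ht$statistic), 6.19422, tolerance = 1e-5)
  expect_equal(unname(ht$parameter), 9)
  expect_equal(ht$p.value, 2 * stats::pt(-t_hand, 9))

  z <- corrected_resampled_ttest(rep(0, 8), 0.1)
  expect_equal(unname(z$statistic), 0)
  expect_equal(z$p.value, 1)

  dg <- corrected_resampled_ttest(rep(2, 5), 0.2)
  expect_identical(unname(dg$statistic), Inf)
  expect_identical(dg$p.value, 0)
  expect_true(dg$degenerate)

  ## the correction can only shrink |t| relative to the standard test
  set.seed(9)
  for (i in 1:10) {
    di <- rnorm(12, mean = 0.3)
    tc <- unname(corrected_resampled_ttest(di, 0.1)$statistic)
    ts <- mean(di) / sqrt(stats::var(di) / length(di))
    expect_lte(abs(tc), abs(ts) + 1e-12)
  }
})

test_that("the protocol is stratified, exhaustive and reproducible", {
  d <- gaussian_features(22, 18, 12, informative = 1:3, delta = 1.5,
                         seed = 6)
  cfg <- protocol_config(folds = 5, repetitions = 3, fs_method = "rfe",
                         n_features_grid = c(2, 6, 12), seed = 11)
  res <- run_protocol(d$x, d$y, cfg)
  ## each subject tested exactly once per repetition
  for (r in 1:3) {
    fr <- Filter(function(f) f$repetition == r, res$folds)
    tested <- sort(unlist(lapply(fr, `[[`, "test_idx")))
    expect_identical(tested, 1:40)
    ## stratification: per-fold class counts within 1 of the cohort ratio
    for (f in fr) {
      n_hr <- sum(d$y[f$test_idx] == "HR")
      expect_lte(abs(n_hr - 22 / 5), 1)
    }
  }
  res2 <- run_protocol(d$x, d$y, cfg)
  expect_identical(res$metrics, res2$metrics)
  expect_identical(res$folds[[7]]$ranking, res2$folds[[7]]$ranking)
  expect_true(all(res$metrics$accuracy_mean >= 0 &
                    res$metrics$accuracy_mean <= 100))
})

test_that("RFE at the full dimension predicts identically to a plain SVM", {
  d <- gaussian_features(12, 12, 8, informative = 1:2, delta = 1.5,
                         seed = 7)
  cfg_rfe <- protocol_config(folds = 4, repetitions = 2, fs_method = "rfe",
                             n_features_grid = 8, seed = 13)
  cfg_none <- protocol_config(folds = 4, repetitions = 2, fs_method = "none",
                              n_features_grid = 8, seed = 13)
  a <- run_protocol(d$x, d$y, cfg_rfe)
  b <- run_protocol(d$x, d$y, cfg_none)
  for (i in seq_along(a$folds))
    expect_identical(a$folds[[i]]$predictions, b$folds[[i]]$predictions)
})

test_that("Y-randomized protocols perform at chance", {
  d <- gaussian_features(20, 20, 6, informative = 1:3, delta = 3, seed = 8)
  cfg <- protocol_config(folds = 5, repetitions = 10, fs_method = "random",
                         n_features_grid = c(3, 6), y_randomize = TRUE,
                         seed = 17)
  res <- run_protocol(d$x, d$y, cfg)
  acc <- mean(res$per_repetition$accuracy)
  expect_gte(acc, 35)
  expect_lte(acc, 65)
  ## the same data without randomization is near-perfect
  cfg2 <- protocol_config(folds = 5, repetitions = 2, fs_method = "none",
                          n_features_grid = 6, seed = 17)
  expect_gte(max(run_protocol(d$x, d$y, cfg2)$metrics$accuracy_mean), 90)
})

test_that("the deployable screening model fits, ranks and predicts", {
  d <- gaussian_features(20, 20, 10, informative = 1:2, delta = 3, seed = 10)
  m <- screen_svm(d$x, d$y, n_features = 4)
  expect_s3_class(m, "screen_svm")
  expect_setequal(m$ranking[1:2], 1:2)
  w <- coef(m)
  expect_length(w, 4)
  expect_named(w)
  pred <- predict(m, d$x)
  expect_gte(unname(classification_metrics(d$y, pred)["accuracy"]), 95)
  expect_output(print(m), "screening classifier")
})
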