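test_that("min-max scaling maps training range to [-1, 1] and extrapolates test", {
  train <- cbind(a = c(0, 10), b = c(5, 5))
  test <- cbind(a = c(15, 5), b = c(7, 5))
  sc <- minmax_scale_fit_apply(train, test)
  expect_equal(unname(sc$train[, "a"]), c(-1, 1))
  # constant training feature maps to 0 everywhere, including test
  expect_equal(unname(sc$train[, "b"]), c(0, 0))
  expect_equal(unname(sc$test[, "b"]), c(0, 0))
  # affine formula: 2 * (15 - 0) / 10 - 1 = 2
  expect_equal(unname(sc$test[, "a"]), c(2, 0))
  # scaler parameters depend only on the training partition
  sc2 <- minmax_scale_fit(train)
  expect_equal(sc$scaler, sc2)
})

test_that("stratified folds balance classes within one subject", {
  y <- factor(rep(c("control", "patient"), each = 72))
  folds <- stratified_folds(y, 10, seed = 5)
  sizes <- table(folds)
  expect_true(all(sizes %in% c(14, 15)))
  per_class <- table(folds, y)
  expect_true(all(per_class %in% c(7, 8)))
  # same seed, same assignment; different seed differs
  expect_identical(folds, stratified_folds(y, 10, seed = 5))
  expect_false(identical(folds, stratified_folds(y, 10, seed = 6)))
  y10 <- factor(rep(c("control", "patient"), each = 10))
  f10 <- stratified_folds(y10, 10, seed = 1)
  expect_true(all(table(f10, y10) == 1))
  expect_error(stratified_folds(factor(rep(c("a", "b"), c(3, 20))), 10, seed = 1),
               "fewer members than folds")
})

test_that("confusion metrics implement the six formulas with NA for 0/0", {
  perfect <- confusion_metrics(tp = 70, tn = 70, fp = 0, fn = 0)
  expect_true(all(perfect == 1))
  m <- confusion_metrics(tp = 3, tn = 4, fp = 2, fn = 1)
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["specificity"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(m["ppv"]), 0.6)
  expect_equal(unname(m["npv"]), 0.8)
  expect_equal(unname(m["f1"]), 2 / 3, tolerance = 1e-12)
  no_pos <- confusion_metrics(tp = 0, tn = 5, fp = 0, fn = 0)
  expect_true(is.na(no_pos["ppv"]))
  expect_error(confusion_metrics(tp = 0, tn = 0, fp = 0, fn = 0), "zero")
})

test_that("nested CV is perfect on separated clusters and keeps its books", {
  d <- separable_data(n_per = 15, d = 4, delta = 5, seed = 3)
  cfg <- cv_config(n_folds = 5, n_repeats = 2, seed = 7)
  res <- nested_cv(d$X, d$y, elm_spec(n_hidden = 10), cfg)
  expect_equal(res$accuracy, 1)
  expect_equal(nrow(res$folds), 10L)
  # partition property: every subject tested exactly once per repeat
  for (r in 1:2) {
    per_rep <- res$folds[res$folds$repeat_ == r, ]
    expect_equal(sum(per_rep$n_test), 30L)
  }
  # bookkeeping identity: pooled accuracy from stored counts
  expect_equal(res$accuracy,
               with(res$folds, sum(tp + tn) / sum(tp + tn + fp + fn)))
})

test_that("the 10x10 default produces one fold record per repeat and fold", {
  d <- separable_data(n_per = 15, d = 3, delta = 2, seed = 9)
  res <- nested_cv(d$X, d$y, elm_spec(n_hidden = 8),
                   cv_config(n_folds = 10, n_repeats = 10, seed = 2))
  expect_equal(nrow(res$folds), 100L)
  expect_equal(sort(unique(res$folds$repeat_)), 1:10)
  expect_equal(sort(unique(res$folds$fold)), 1:10)
})

test_that("nested CV equals an explicit manual loop fold for fold", {
  d <- separable_data(n_per = 5, d = 3, delta = 1, seed = 13)
  cfg <- cv_config(n_folds = 2, n_repeats = 1, seed = 19)
  spec <- elm_spec(n_hidden = 7)
  res <- nested_cv(d$X, d$y, spec, cfg)

  folds <- stratified_folds(d$y, 2, seed = cv_repeat_seed(19, 1))
  for (f in 1:2) {
    tr <- folds != f
    sc <- minmax_scale_fit_apply(d$X[tr, , drop = FALSE],
                                 d$X[!tr, , drop = FALSE])
    fit <- elm_train(sc$train, d$y[tr], 7, seed = cv_fold_seed(19, 1, f))
    pred <- elm_predict(fit, sc$test)
    truth <- d$y[!tr]
    row <- res$folds[res$folds$fold == f, ]
    expect_identical(row$tp, sum(pred == "patient" & truth == "patient"))
    expect_identical(row$tn, sum(pred == "control" & truth == "control"))
    expect_identical(row$fp, sum(pred == "patient" & truth == "control"))
    expect_identical(row$fn, sum(pred == "control" & truth == "patient"))
  }
})

test_that("global scaling mode fits the scaler once on everything", {
  set.seed(23)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- factor(rep(c("control", "patient"), 20))
  cfg_g <- cv_config(n_folds = 4, n_repeats = 1, seed = 3,
                     scaling_mode = "global")
  res <- nested_cv(X, y, elm_spec(n_hidden = 10), cfg_g)
  expect_s3_class(res, "cv_result")
  expect_equal(nrow(res$folds), 4L)
})

test_that("permutation test uses the add-one estimator on a real run", {
  d <- separable_data(n_per = 8, d = 4, delta = 6, seed = 5)
  cfg <- cv_config(n_folds = 4, n_repeats = 1, seed = 2)
  res <- permutation_test(d$X, d$y, elm_spec(n_hidden = 10), cfg,
                          n_permutations = 99, seed = 31)
  expect_equal(res$observed_stat, 1)
  expect_equal(res$p_value,
               (1 + res$n_as_extreme) / (1 + res$n_permutations))
  # wide separation: permuted labels cannot reach perfect accuracy
  expect_equal(res$n_as_extreme, 0L)
  expect_equal(res$p_value, 0.01)
  expect_lte(res$p_value, 1)
  expect_gt(res$p_value, 0)
})

test_that("RNG state of the caller is never disturbed", {
  set.seed(99)
  before <- .Random.seed
  d <- separable_data(n_per = 5, d = 2, delta = 3, seed = 1)
  set.seed(99)
  invisible(nested_cv(d$X, d$y, elm_spec(n_hidden = 5),
                      cv_config(n_folds = 2, n_repeats = 1, seed = 4)))
  expect_identical(.Random.seed, before)
})
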