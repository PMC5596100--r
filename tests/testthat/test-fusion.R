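test_that("the weight formula down-weights by accuracy deficit only", {
  w <- compute_weights(c(a = 1.0, b = 0.5))
  expect_equal(unname(w$weights), c(1.0, 0.5))
  equal <- compute_weights(c(a = 0.8, b = 0.8, c = 0.8))
  expect_true(all(equal$weights == 1))
  # shift-consistency: weights depend only on A_i - A_max
  set.seed(41)
  for (i in 1:10) {
    a <- runif(6, 0.4, 0.9)
    names(a) <- paste0("m", 1:6)
    w1 <- compute_weights(a)
    w2 <- compute_weights(a + 0.05)
    expect_equal(w1$weights, w2$weights, tolerance = 1e-12)
    # the arg-max measure always has weight exactly 1
    expect_identical(unname(w1$weights[which.max(a)]), 1)
    expect_true(all(w1$weights >= 0 & w1$weights <= 1))
  }
  expect_error(compute_weights(c(a = 1.2)), "\\[0, 1\\]")
  expect_error(accuracy_vector(numeric(0)), "at least one")
})

test_that("simple concatenation preserves block order and columns", {
  labels <- subject_labels(c("s1", "s2", "s3"),
                           c("control", "control", "patient"))
  m1 <- mk_measure(matrix(1, 3, 2), "m1")
  m2 <- mk_measure(matrix(2, 3, 2), "m2", group = "subcortical")
  ds <- assemble_dataset(list(m1, m2), labels)
  X <- simple_concat(ds)
  expect_equal(dim(X), c(3L, 4L))
  expect_equal(unname(X[1, ]), c(1, 1, 2, 2))
  expect_equal(simple_concat(ds, "m1"), m1$values)
  expect_error(simple_concat(ds, "nope"), "unknown measure")
})

test_that("simple weighted concatenation multiplies blocks by their weights", {
  labels <- subject_labels(c("s1", "s2"), c("control", "patient"))
  ones <- mk_measure(matrix(1, 2, 1), "ones")
  other <- mk_measure(matrix(3, 2, 2), "other", group = "subcortical")
  ds <- assemble_dataset(list(ones, other), labels)
  w_id <- compute_weights(c(ones = 0.9, other = 0.9))   # both weights 1
  expect_equal(simple_weighted_concat(ds, w_id), simple_concat(ds))
  w <- compute_weights(c(ones = 0.4, other = 0.9))      # ones -> 0.5
  fused <- simple_weighted_concat(ds, w)
  expect_equal(unname(fused[, 1]), c(0.5, 0.5))
  # element-wise recomputation on a random dataset
  set.seed(51)
  ds2 <- toy_dataset(n_per = 6, seed = 51)
  keys <- unique(vapply(ds2$measures, function(m) m$weight_key, character(1)))
  acc <- setNames(runif(length(keys), 0.5, 0.95), keys)
  w2 <- compute_weights(acc)
  fused2 <- simple_weighted_concat(ds2, w2)
  start <- 1L
  for (m in ds2$measures) {
    cols <- start:(start + ncol(m$values) - 1L)
    expect_equal(unname(fused2[, cols]),
                 unname(w2$weights[[m$weight_key]] * m$values),
                 tolerance = 1e-12)
    start <- start + ncol(m$values)
  }
  w_missing <- compute_weights(c(ones = 0.9))
  expect_error(simple_weighted_concat(ds, w_missing), "no weight")
})

test_that("hybrid concatenation normalizes blocks by their summed weights", {
  labels <- subject_labels(c("s1", "s2"), c("control", "patient"))
  # single measure per block: w/sum(w) = 1, block passes through unchanged
  ds1 <- assemble_dataset(list(
    mk_measure(matrix(c(1, 2), 2, 1), "cort", group = "cortical"),
    mk_measure(matrix(c(3, 4), 2, 1), "sc", group = "subcortical"),
    mk_measure(matrix(c(5, 6), 2, 1), "ica", group = "gica")), labels)
  w1 <- compute_weights(c(cort = 0.6, sc = 0.9, ica = 0.7))
  H1 <- hybrid_weighted_concat(ds1, w1)
  expect_equal(unname(H1[, 1]), c(1, 2))
  expect_equal(unname(H1[, 2]), c(3, 4))
  expect_equal(unname(H1[, 3]), c(5, 6))  # gICA appended unweighted
  # two cortical measures, weights 1 and 3, unit inputs -> w_i / sum(w)
  ds2 <- assemble_dataset(list(
    mk_measure(matrix(1, 2, 1), "c1", group = "cortical"),
    mk_measure(matrix(1, 2, 1), "c2", group = "cortical"),
    mk_measure(matrix(1, 2, 1), "sc", group = "subcortical")), labels)
  w2 <- structure(list(weights = c(c1 = 1, c2 = 3, sc = 1),
                       accuracy = NULL, a_max = NA), class = "weight_vector")
  H2 <- hybrid_weighted_concat(ds2, w2)
  expect_equal(unname(H2[1, 1:2]), c(0.25, 0.75))
  # equal weights reduce each block to (1/k) * block
  ds3 <- assemble_dataset(list(
    mk_measure(matrix(rnorm(4), 2, 2), "c1", group = "cortical"),
    mk_measure(matrix(rnorm(4), 2, 2), "c2", group = "cortical"),
    mk_measure(matrix(rnorm(4), 2, 2), "s1", group = "subcortical")), labels)
  w3 <- compute_weights(c(c1 = 0.8, c2 = 0.8, s1 = 0.8))
  H3 <- hybrid_weighted_concat(ds3, w3)
  expect_equal(unname(H3[, 1:4]),
               unname(cbind(ds3$measures$c1$values, ds3$measures$c2$values) / 2),
               tolerance = 1e-12)
  # degenerate designs are rejected
  ds_nosc <- assemble_dataset(list(
    mk_measure(matrix(1, 2, 1), "c1", group = "cortical")), labels)
  expect_error(hybrid_weighted_concat(ds_nosc, w1), "subcortical")
})

test_that("whole-brain measures share subcortical weights counted once", {
  labels <- subject_labels(c("s1", "s2"), c("control", "patient"))
  ds <- assemble_dataset(list(
    mk_measure(matrix(1, 2, 1), "cort", group = "cortical"),
    mk_measure(matrix(1, 2, 1), "SC Int", group = "subcortical"),
    mk_measure(matrix(1, 2, 1), "WB Int", group = "wholebrain",
               weight_key = "SC Int"),
    mk_measure(matrix(1, 2, 1), "Overall", group = "wholebrain")), labels)
  w <- structure(list(weights = c(cort = 1, `SC Int` = 0.5, Overall = 0.5),
                      accuracy = NULL, a_max = NA), class = "weight_vector")
  H <- hybrid_weighted_concat(ds, w)
  # block sum counts the shared 0.5 once: denominator 0.5 + 0.5 = 1
  expect_equal(unname(H[1, 2:4]), c(0.5, 0.5, 0.5))
})

test_that("concatenations preserve rows, order, and column additivity", {
  ds <- toy_dataset(n_per = 6, seed = 3)
  keys <- unique(vapply(ds$measures, function(m) m$weight_key, character(1)))
  w <- compute_weights(setNames(runif(length(keys), 0.6, 0.95), keys))
  total <- total_feature_count(ds)
  for (X in list(simple_concat(ds), simple_weighted_concat(ds, w),
                 hybrid_weighted_concat(ds, w))) {
    expect_equal(nrow(X), 12L)
    expect_equal(ncol(X), total)
    expect_equal(rownames(X), ds$labels$subject_ids)
  }
})

test_that("per-measure accuracy separates signal from noise measures", {
  ds <- toy_dataset(n_per = 20, seed = 7,
                    effects = c(cortA = 4, cortB = 0, scA = 0, scB = 0,
                                ica = 0))
  cfg <- cv_config(n_folds = 5, n_repeats = 1, seed = 11)
  acc <- per_measure_accuracy(ds, elm_spec(n_hidden = 20), cfg)
  expect_gte(acc$accuracy[["cortA"]], 0.9)
  nulls <- acc$accuracy[c("cortB", "scA", "scB", "ica")]
  expect_true(all(abs(nulls - 0.5) <= 0.2))
  # deterministic given seeds
  acc2 <- per_measure_accuracy(ds, elm_spec(n_hidden = 20), cfg)
  expect_identical(acc$accuracy, acc2$accuracy)
  # the informative measure takes weight exactly 1
  w <- compute_weights(acc)
  expect_identical(unname(w$weights[["cortA"]]), 1)
})
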