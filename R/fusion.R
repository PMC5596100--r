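# Accuracy-driven weighted feature concatenation. Weights derive from
# per-measure cross-validated accuracies: the best measure gets weight 1,
# every other measure is down-weighted by exactly its accuracy deficit.

#' Per-measure cross-validated accuracies
#'
#' Runs [nested_cv()] independently on each measure's feature block and
#' returns the pooled test accuracy per fusion weight key. Measures sharing
#' a weight key (e.g. a subcortical and a whole-brain block of the same
#' quantity) are concatenated and evaluated as one measure, so the result
#' has one accuracy per distinct key.
#'
#' @param dataset A [assemble_dataset()] result.
#' @param spec An [elm_spec()].
#' @param config A [cv_config()].
#' @return An object of class `accuracy_vector`: named `accuracy` vector (by
#'   weight key, in first-appearance order), `a_max`, and `residuals`
#'   (`a_max - accuracy`).
#' @export
per_measure_accuracy <- function(dataset, spec, config = cv_config()) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  keys <- unique(vapply(dataset$measures, function(m) m$weight_key, character(1)))
  acc <- vapply(keys, function(k) {
    blocks <- Filter(function(m) m$weight_key == k, dataset$measures)
    X <- do.call(cbind, lapply(blocks, function(m) m$values))
    nested_cv(X, dataset$labels, spec, config)$accuracy
  }, numeric(1))
  accuracy_vector(acc)
}

#' Construct an accuracy vector
#'
#' @param accuracy Named numeric vector of per-measure accuracies in [0, 1].
#' @return An object of class `accuracy_vector` with `accuracy`, `a_max`
#'   (the maximum) and `residuals` (`a_max - accuracy`, each in [0, 1]).
#' @export
accuracy_vector <- function(accuracy) {
  accuracy <- unlist(accuracy)
  if (length(accuracy) < 1L) stopf("at least one accuracy is required")
  if (is.null(names(accuracy)) || any(!nzchar(names(accuracy)))) {
    stopf("accuracies must be named by measure")
  }
  if (any(!is.finite(accuracy)) || any(accuracy < 0 | accuracy > 1)) {
    stopf("accuracies must lie in [0, 1]")
  }
  a_max <- max(accuracy)
  structure(list(accuracy = accuracy, a_max = a_max,
                 residuals = a_max - accuracy),
            class = "accuracy_vector")
}

#' Fusion weights from per-measure accuracies
#'
#' The weighting rule of the fusion scheme: with `A_max` the best
#' per-measure accuracy, each measure's residual is `R_i = A_max - A_i` and
#' its weight `W_i = 1 - R_i = 1 - A_max + A_i`. The most accurate measure
#' therefore always gets weight exactly 1; every other weight is 1 minus its
#' accuracy deficit, and all weights lie in [0, 1]. Weights depend only on
#' accuracy differences, so adding a constant to every accuracy leaves them
#' unchanged. Full precision is retained; round only for display.
#'
#' @param acc An [accuracy_vector()] (or a named numeric vector of
#'   accuracies in [0, 1]).
#' @return An object of class `weight_vector`: named `weights`, the source
#'   `accuracy` and `a_max`.
#' @examples
#' compute_weights(c(Thickness = 0.91, `Group ICA` = 0.93))
#' @export
compute_weights <- function(acc) {
  if (!inherits(acc, "accuracy_vector")) acc <- accuracy_vector(acc)
  w <- 1 - acc$residuals
  structure(list(weights = w, accuracy = acc$accuracy, a_max = acc$a_max),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  ord <- order(-x$weights)
  df <- data.frame(rank = seq_along(ord),
                   measure = names(x$weights)[ord],
                   accuracy = round(x$accuracy[ord], 4),
                   weight = round(x$weights[ord], 4))
  cat("<weight_vector>\n")
  print(df, row.names = FALSE)
  invisible(x)
}

# Resolve a measure subset argument to the dataset's measure labels,
# preserving dataset order.
resolve_measures <- function(dataset, measures) {
  all_labels <- names(dataset$measures)
  if (is.null(measures)) return(all_labels)
  unknown <- setdiff(measures, all_labels)
  if (length(unknown)) {
    stopf("unknown measure label(s): %s", paste(unknown, collapse = ", "))
  }
  all_labels[all_labels %in% measures]
}

# Look up the fusion weight for one measure via its weight key.
measure_weight <- function(m, weights) {
  if (!m$weight_key %in% names(weights$weights)) {
    stopf("no weight for measure '%s' (weight key '%s')", m$label, m$weight_key)
  }
  weights$weights[[m$weight_key]]
}

#' Simple feature concatenation
#'
#' Column-binds the measures' feature blocks in dataset order. No scaling is
#' performed here: in the fusion pipeline each measure is min-max scaled to
#' [-1, 1] *before* any concatenation or weighting (see [scale_dataset()]),
#' and the fused matrix is not rescaled afterwards — rescaling per feature
#' after weighting would cancel the weights exactly.
#'
#' @param dataset A [assemble_dataset()] result.
#' @param measures Optional character vector of measure labels to include
#'   (default: all, in dataset order).
#' @return Numeric matrix, subjects x total features.
#' @export
simple_concat <- function(dataset, measures = NULL) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  labels <- resolve_measures(dataset, measures)
  if (length(labels) == 0L) stopf("empty measure subset")
  do.call(cbind, lapply(dataset$measures[labels], function(m) m$values))
}

#' Simple weighted feature concatenation
#'
#' Multiplies each measure's (pre-scaled) feature block by its scalar fusion
#' weight and concatenates the blocks in dataset order. No block
#' normalization is applied (contrast [hybrid_weighted_concat()]).
#'
#' @param dataset A [assemble_dataset()] result, normally already scaled via
#'   [scale_dataset()].
#' @param weights A [compute_weights()] result covering every measure's
#'   weight key.
#' @return Numeric matrix with the same shape as [simple_concat()].
#' @export
simple_weighted_concat <- function(dataset, weights) {
  stopifnot(inherits(dataset, "multimodal_dataset"),
            inherits(weights, "weight_vector"))
  do.call(cbind, lapply(dataset$measures, function(m) {
    measure_weight(m, weights) * m$values
  }))
}

#' Hybrid weighted feature concatenation
#'
#' The anatomically blocked variant of weighted fusion. Cortical measures
#' are weighted, concatenated, and divided by the sum of the cortical
#' weights; subcortical and whole-brain measures form the second block,
#' likewise weighted and divided by the sum of the distinct weights used in
#' it (whole-brain blocks that share a weight key with a subcortical measure
#' reuse its weight, which is counted once in the sum); ICA connectivity
#' features are appended unweighted. Column counts and order are identical
#' to [simple_concat()].
#'
#' @inheritParams simple_weighted_concat
#' @return Numeric matrix, subjects x total features, columns grouped
#'   cortical block, subcortical + whole-brain block, then gICA.
#' @export
hybrid_weighted_concat <- function(dataset, weights) {
  stopifnot(inherits(dataset, "multimodal_dataset"),
            inherits(weights, "weight_vector"))
  groups <- vapply(dataset$measures, function(m) m$group, character(1))
  cortical <- dataset$measures[groups == "cortical"]
  subcort <- dataset$measures[groups %in% c("subcortical", "wholebrain")]
  gica <- dataset$measures[groups == "gica"]
  if (length(cortical) == 0L) stopf("no cortical measures: hybrid blocking is degenerate")
  if (length(subcort) == 0L) stopf("no subcortical measures: hybrid blocking is degenerate")
  block <- function(ms) {
    w_used <- vapply(ms, function(m) measure_weight(m, weights), numeric(1))
    keys <- vapply(ms, function(m) m$weight_key, character(1))
    total <- sum(w_used[!duplicated(keys)])
    do.call(cbind, Map(function(m, w) w * m$values, ms, w_used)) / total
  }
  out <- cbind(block(cortical), block(subcort))
  if (length(gica) > 0L) {
    out <- cbind(out, do.call(cbind, lapply(gica, function(m) m$values)))
  }
  out
}

#' Min-max scale every measure of a dataset to [-1, 1]
#'
#' Fits a per-feature [-1, 1] scaler on each measure (over all subjects) and
#' applies it, returning a new dataset. This is the whole-dataset scaling
#' variant; the leakage-free alternative fits scalers per CV training fold
#' (see [fused_nested_cv()]).
#'
#' @param dataset A [assemble_dataset()] result.
#' @return A `multimodal_dataset` with scaled values.
#' @export
scale_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  dataset$measures <- lapply(dataset$measures, function(m) {
    m$values <- minmax_scale_fit_apply(m$values)$train
    dimnames(m$values) <- list(m$subject_ids, m$feature_names)
    m
  })
  dataset
}

# Fuse pre-scaled train/test measure lists with one of the three methods.
fuse_blocks <- function(measures, labels_obj, method, weights) {
  ds <- structure(list(measures = measures, labels = labels_obj),
                  class = "multimodal_dataset")
  switch(method,
         simple = simple_concat(ds),
         weighted = simple_weighted_concat(ds, weights),
         hybrid = hybrid_weighted_concat(ds, weights))
}

#' Nested cross-validation of a fused multimodal classifier
#'
#' Evaluates the full fusion pipeline under stratified repeated CV. Two
#' weighting protocols are available:
#'
#' * `weight_mode = "within_fold"` (default, leakage-free): inside every
#'   outer training partition, per-measure accuracies are estimated by a
#'   secondary CV on the training subjects only (`weight_config`), weights
#'   computed, measures scaled on the training partition, fused, and the
#'   classifier trained — the held-out fold touches nothing upstream.
#' * `weight_mode = "whole_dataset"`: per-measure accuracies and weights are
#'   computed once from the complete dataset (as published weight tables
#'   are), each measure is scaled over all subjects, and the fused matrix is
#'   cross-validated. Faster and matches the published protocol, but test
#'   subjects inform the weights and scaler.
#'
#' @param dataset A [assemble_dataset()] result (unscaled).
#' @param method `"simple"`, `"weighted"` or `"hybrid"`.
#' @param spec An [elm_spec()] for the fused-matrix classifier.
#' @param config A [cv_config()] for the outer evaluation.
#' @param weight_mode See above.
#' @param weight_config A [cv_config()] for the per-measure accuracy
#'   estimation (defaults to a light 5-fold, 1-repeat config; ignored for
#'   `method = "simple"`).
#' @param weight_spec An [elm_spec()] for per-measure accuracy estimation
#'   (defaults to `spec` without its search range, for speed).
#' @return A list: `cv` (a `cv_result` for the fused classifier), `weights`
#'   (a `weight_vector` for `"whole_dataset"`, or the per-fold weight table
#'   for `"within_fold"`), `method`, `weight_mode`.
#' @export
fused_nested_cv <- function(dataset, method = c("hybrid", "weighted", "simple"),
                            spec = elm_spec(), config = cv_config(),
                            weight_mode = c("within_fold", "whole_dataset"),
                            weight_config = NULL, weight_spec = NULL) {
  method <- match.arg(method)
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(dataset, "multimodal_dataset"))
  if (is.null(weight_config)) {
    weight_config <- cv_config(n_folds = 5L, n_repeats = 1L,
                               seed = config$seed + 1L,
                               scaling_mode = config$scaling_mode,
                               tuning_mode = "inner",
                               inner_folds = config$inner_folds,
                               stratified = config$stratified)
  }
  if (is.null(weight_spec)) {
    weight_spec <- elm_spec(n_hidden = spec$n_hidden, activation = spec$activation)
  }
  y <- dataset$labels$diagnosis

  if (method == "simple" || weight_mode == "whole_dataset") {
    weights <- NULL
    if (method != "simple") {
      weights <- compute_weights(per_measure_accuracy(dataset, weight_spec,
                                                      weight_config))
    }
    scaled <- scale_dataset(dataset)
    X <- fuse_blocks(scaled$measures, dataset$labels, method, weights)
    # blocks are already scaled and weighted: never rescale the fused
    # matrix per feature, which would cancel the weights exactly
    cfg <- config
    cfg$scaling_mode <- "none"
    cv <- nested_cv(X, y, spec, cfg)
    return(list(cv = cv, weights = weights, method = method,
                weight_mode = if (method == "simple") NA_character_ else weight_mode))
  }

  # within_fold: the outer loop re-derives scalers and weights per fold
  metric_names <- c("accuracy", "sensitivity", "specificity", "npv", "ppv", "f1")
  rows <- list(); weight_rows <- list(); k <- 0L
  pos <- levels(y)[2L]
  for (r in seq_len(config$n_repeats)) {
    folds <- stratified_folds(y, config$n_folds,
                              seed = cv_repeat_seed(config$seed, r),
                              stratified = config$stratified)
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      train_meas <- lapply(dataset$measures, function(m) {
        m$values <- m$values[tr, , drop = FALSE]
        m$subject_ids <- m$subject_ids[tr]
        m
      })
      train_labels <- subject_labels(dataset$labels$subject_ids[tr],
                                     as.character(y[tr]),
                                     class_levels = levels(y))
      train_ds <- structure(list(measures = train_meas, labels = train_labels),
                            class = "multimodal_dataset")
      weights <- compute_weights(per_measure_accuracy(train_ds, weight_spec,
                                                      weight_config))
      # scale each measure on the training partition, apply to held-out fold
      scaled_train <- dataset$measures; scaled_test <- dataset$measures
      for (nm in names(dataset$measures)) {
        sc <- minmax_scale_fit_apply(
          dataset$measures[[nm]]$values[tr, , drop = FALSE],
          dataset$measures[[nm]]$values[!tr, , drop = FALSE])
        scaled_train[[nm]]$values <- sc$train
        scaled_train[[nm]]$subject_ids <- dataset$labels$subject_ids[tr]
        scaled_test[[nm]]$values <- sc$test
        scaled_test[[nm]]$subject_ids <- dataset$labels$subject_ids[!tr]
      }
      test_labels <- subject_labels(dataset$labels$subject_ids[!tr],
                                    as.character(y[!tr]),
                                    class_levels = levels(y))
      X_train <- fuse_blocks(scaled_train, train_labels, method, weights)
      X_test <- fuse_blocks(scaled_test, test_labels, method, weights)
      fseed <- cv_fold_seed(config$seed, r, f)
      cfg_fold <- config
      cfg_fold$scaling_mode <- "none"  # blocks are already fold-scaled
      res <- fit_predict_fold(spec, X_train, y[tr], X_test, y[!tr],
                              cfg_fold, fseed)
      truth <- y[!tr]
      counts <- c(tp = sum(res$pred == pos & truth == pos),
                  tn = sum(res$pred != pos & truth != pos),
                  fp = sum(res$pred == pos & truth != pos),
                  fn = sum(res$pred != pos & truth == pos))
      k <- k + 1L
      rows[[k]] <- data.frame(
        repeat_ = r, fold = f, n_test = sum(!tr), n_hidden = res$n_hidden,
        tp = counts[["tp"]], tn = counts[["tn"]],
        fp = counts[["fp"]], fn = counts[["fn"]],
        train_accuracy = mean(res$train_pred == y[tr]),
        t(confusion_metrics(counts)))
      weight_rows[[k]] <- data.frame(repeat_ = r, fold = f,
                                     measure = names(weights$weights),
                                     weight = unname(weights$weights),
                                     row.names = NULL)
    }
  }
  folds_df <- do.call(rbind, rows)
  metrics <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(folds_df[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_names, function(m) stats::sd(folds_df[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  cv <- structure(
    list(folds = folds_df, metrics = metrics,
         accuracy = with(folds_df, sum(tp + tn) / sum(tp + tn + fp + fn)),
         train_accuracy = mean(folds_df$train_accuracy),
         classes = levels(y), config = config),
    class = "cv_result")
  list(cv = cv, weights = do.call(rbind, weight_rows), method = method,
       weight_mode = weight_mode)
}
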