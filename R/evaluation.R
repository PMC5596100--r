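#' Cross-validation configuration
#'
#' Settings for stratified repeated ("10-by-10") nested cross-validation.
#'
#' @param n_folds Outer folds per repeat (>= 2; default 10).
#' @param n_repeats Independent repetitions of the k-fold split (default 10).
#' @param seed Master seed; fold assignment for repeat r uses
#'   [cv_repeat_seed()] and classifier randomness in repeat r, fold f uses
#'   [cv_fold_seed()], so any fold is reproducible in isolation.
#' @param scaling_mode `"per_fold_train"` (default) fits the [-1, 1] scaler
#'   on each training partition only and applies it to the held-out fold —
#'   no information from test subjects reaches the scaler. `"global"` fits
#'   the scaler once on the full matrix before splitting, replicating the
#'   common (leaky) practice of normalizing the whole dataset up front.
#'   `"none"` passes the matrix through untouched — required for fused
#'   matrices whose blocks are already scaled and weighted, since
#'   re-scaling per feature would cancel the fusion weights exactly.
#' @param tuning_mode `"inner"` (default) selects hyperparameters by
#'   stratified CV inside each training partition. `"paper_replication"`
#'   selects them by accuracy on the outer held-out fold, reproducing a
#'   tune-on-test protocol; use it only to replicate published figures.
#' @param inner_folds Folds for the inner tuning CV (default 5).
#' @param stratified Stratify fold assignment by class (default TRUE).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, n_repeats = 10L, seed = 1L,
                      scaling_mode = c("per_fold_train", "global", "none"),
                      tuning_mode = c("inner", "paper_replication"),
                      inner_folds = 5L, stratified = TRUE) {
  scaling_mode <- match.arg(scaling_mode)
  tuning_mode <- match.arg(tuning_mode)
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  if (n_repeats < 1L) stopf("n_repeats must be >= 1")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed),
                 scaling_mode = scaling_mode,
                 tuning_mode = tuning_mode,
                 inner_folds = as.integer(inner_folds),
                 stratified = isTRUE(stratified)),
            class = "cv_config")
}

#' Fit a min-max scaler mapping training range to [-1, 1]
#'
#' Per feature, an affine map sending the training minimum to -1 and the
#' training maximum to +1. Constant training features are mapped to 0
#' everywhere (slope 0), never dividing by a zero range.
#'
#' @param train Numeric training matrix (rows = subjects).
#' @return An object of class `minmax_scaler` with `center` and `slope`.
#' @seealso [minmax_scale_apply()], [minmax_scale_fit_apply()]
#' @export
minmax_scale_fit <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 1L) stopf("training matrix is empty")
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  rng <- hi - lo
  const <- rng <= 0
  slope <- ifelse(const, 0, 2 / rng)
  center <- ifelse(const, 0, (lo + hi) / 2)
  structure(list(center = center, slope = slope), class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Test values outside the training range map beyond [-1, 1]; they are not
#' clipped.
#'
#' @param scaler A [minmax_scale_fit()] result.
#' @param X Matrix with the same columns as the training matrix.
#' @return Scaled matrix.
#' @export
minmax_scale_apply <- function(scaler, X) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  X <- as.matrix(X)
  if (ncol(X) != length(scaler$slope)) {
    stopf("X has %d columns, scaler was fitted on %d", ncol(X), length(scaler$slope))
  }
  sweep(sweep(X, 2L, scaler$center, "-"), 2L, scaler$slope, "*")
}

#' Fit a [-1, 1] scaler on training data and apply it to train and test
#'
#' @param train Training matrix (scaler is fitted here only).
#' @param test Test matrix (same columns; may be NULL).
#' @return List with `train`, `test`, and the fitted `scaler`.
#' @export
minmax_scale_fit_apply <- function(train, test = NULL) {
  scaler <- minmax_scale_fit(train)
  list(train = minmax_scale_apply(scaler, train),
       test = if (!is.null(test)) minmax_scale_apply(scaler, test),
       scaler = scaler)
}

#' Stratified fold assignment
#'
#' Assigns each subject to one of `n_folds` folds so that per-class counts
#' across folds differ by at most one. Deterministic given the seed.
#'
#' @param y Class labels (factor or [subject_labels()]).
#' @param n_folds Number of folds; every class must have at least this many
#'   members when `stratified = TRUE`.
#' @param seed Integer seed.
#' @param stratified If FALSE, plain random folds balanced only in total
#'   size.
#' @return Integer vector of fold indices (1..n_folds), one per subject.
#' @export
stratified_folds <- function(y, n_folds, seed, stratified = TRUE) {
  if (inherits(y, "subject_labels")) y <- y$diagnosis
  y <- as.factor(y)
  n <- length(y)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  folds <- integer(n)
  if (stratified) {
    small <- table(y) < n_folds
    if (any(small)) {
      stopf("class '%s' has fewer members than folds (%d < %d)",
            names(which(small))[1], min(table(y)), n_folds)
    }
    with_seed(seed, {
      load <- integer(n_folds)
      for (cl in levels(y)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        base <- length(idx) %/% n_folds
        extra <- length(idx) %% n_folds
        # remainders go to the currently least-loaded folds (random ties)
        # so total fold sizes never differ by more than one
        per_fold <- rep(base, n_folds)
        if (extra > 0L) {
          ord <- order(load, sample.int(n_folds))
          per_fold[ord[seq_len(extra)]] <- base + 1L
        }
        folds[idx] <- rep(seq_len(n_folds), times = per_fold)
        load <- load + per_fold
      }
    })
  } else {
    if (n < n_folds) stopf("fewer subjects than folds")
    with_seed(seed, {
      folds <- rep_len(seq_len(n_folds), n)[sample.int(n)]
    })
  }
  folds
}

#' Confusion-matrix performance metrics
#'
#' The six standard binary metrics computed from confusion counts, with the
#' positive class being the second class level (patients in a case--control
#' design):
#' accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity TP/(TP+FN), specificity
#' TN/(FP+TN), NPV TN/(FN+TN), PPV TP/(TP+FP), F1 2TP/(2TP+FP+FN). Any 0/0
#' ratio is reported as `NA` (undefined) and excluded from cross-fold
#' aggregation.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts; alternatively pass a
#'   list/vector with those names as `tp`.
#' @return Named numeric vector (accuracy, sensitivity, specificity, npv,
#'   ppv, f1); entries may be `NA` where undefined.
#' @export
confusion_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.list(tp) || (is.numeric(tp) && length(tp) == 4L && !is.null(names(tp)))) {
    counts <- tp
    tp <- counts[["tp"]]; tn <- counts[["tn"]]
    fp <- counts[["fp"]]; fn <- counts[["fn"]]
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) stopf("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, fp + tn),
    npv = ratio(tn, fn + tn),
    ppv = ratio(tp, tp + fp),
    f1 = ratio(2 * tp, 2 * tp + fp + fn))
}

# Train/tune an elm_spec on one training partition and predict the test
# partition. Returns predicted labels and the hidden-node count used.
fit_predict_fold <- function(spec, X_train, y_train, X_test, y_test,
                             config, fold_seed) {
  stopifnot(inherits(spec, "elm_spec"))
  if (is.null(spec$search_range)) {
    nh <- spec$n_hidden
  } else if (config$tuning_mode == "inner") {
    nh <- tune_hidden_nodes(X_train, y_train, spec$search_range,
                            n_folds = config$inner_folds, seed = fold_seed,
                            activation = spec$activation)$n_hidden
  } else {
    # paper_replication: pick the candidate maximizing held-out accuracy
    acc <- vapply(spec$search_range, function(cand) {
      fit <- elm_train(X_train, y_train, cand, seed = fold_seed,
                       activation = spec$activation)
      mean(elm_predict(fit, X_test) == y_test)
    }, numeric(1))
    nh <- spec$search_range[which.max(acc)]
  }
  fit <- elm_train(X_train, y_train, nh, seed = fold_seed,
                   activation = spec$activation)
  list(pred = elm_predict(fit, X_test),
       train_pred = elm_predict(fit, X_train),
       n_hidden = nh)
}

#' Stratified repeated nested cross-validation
#'
#' Runs `n_repeats` independent stratified `n_folds`-fold cross-validations.
#' Within each training partition the feature scaler is fitted (per
#' `scaling_mode`) and the classifier's hidden-node count selected (per
#' `tuning_mode`), the model is trained, and the held-out fold predicted;
#' per-fold confusion counts are recorded. The "10-by-10" protocol is the
#' default `cv_config()`.
#'
#' @param X Numeric feature matrix (subjects x features), unscaled.
#' @param y Class labels ([subject_labels()] or two-level factor), aligned
#'   with the rows of `X`.
#' @param spec An [elm_spec()].
#' @param config A [cv_config()].
#' @return An object of class `cv_result`: `folds` (one row per repeat x
#'   fold with confusion counts, per-fold metrics, chosen `n_hidden`, and
#'   train accuracy), `metrics` (mean and sd of each metric across folds,
#'   undefined ratios excluded), `accuracy` (count-weighted test accuracy
#'   pooled over all folds), `train_accuracy`, and the `config`.
#' @export
nested_cv <- function(X, y, spec, config = cv_config()) {
  if (inherits(y, "subject_labels")) y <- y$diagnosis
  y <- droplevels(as.factor(y))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stopf("X rows and labels differ in length")
  if (nlevels(y) != 2L) stopf("two classes are required")
  if (config$scaling_mode == "global") {
    X_global <- minmax_scale_fit_apply(X)$train
  }
  rows <- vector("list", config$n_folds * config$n_repeats)
  k <- 0L
  for (r in seq_len(config$n_repeats)) {
    folds <- stratified_folds(y, config$n_folds,
                              seed = cv_repeat_seed(config$seed, r),
                              stratified = config$stratified)
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      if (config$scaling_mode == "per_fold_train") {
        sc <- minmax_scale_fit_apply(X[tr, , drop = FALSE],
                                     X[!tr, , drop = FALSE])
        X_train <- sc$train; X_test <- sc$test
      } else if (config$scaling_mode == "global") {
        X_train <- X_global[tr, , drop = FALSE]
        X_test <- X_global[!tr, , drop = FALSE]
      } else {
        X_train <- X[tr, , drop = FALSE]
        X_test <- X[!tr, , drop = FALSE]
      }
      fseed <- cv_fold_seed(config$seed, r, f)
      res <- tryCatch(
        fit_predict_fold(spec, X_train, y[tr], X_test, y[!tr], config, fseed),
        error = function(e) stopf("classifier failed in repeat %d, fold %d: %s",
                                  r, f, conditionMessage(e)))
      pos <- levels(y)[2L]
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
    }
  }
  folds_df <- do.call(rbind, rows)
  metric_names <- c("accuracy", "sensitivity", "specificity", "npv", "ppv", "f1")
  metrics <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(folds_df[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_names, function(m) stats::sd(folds_df[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  structure(
    list(folds = folds_df,
         metrics = metrics,
         accuracy = with(folds_df, sum(tp + tn) / sum(tp + tn + fp + fn)),
         train_accuracy = mean(folds_df$train_accuracy),
         classes = levels(y),
         config = config),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d x %d-fold CV, pooled test accuracy %.4f (train %.4f)\n",
              x$config$n_repeats, x$config$n_folds, x$accuracy, x$train_accuracy))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Permutation test of cross-validated accuracy
#'
#' Assesses the significance of a classifier's cross-validated accuracy by
#' rerunning the identical nested-CV procedure (same config, same seeds —
#' scaling, tuning and training are all repeated) on randomly permuted class
#' labels. The p-value uses the add-one estimator
#' `p = (1 + #\{permuted >= observed\}) / (1 + n_permutations)`, which can
#' never return 0 and is conservative under ties; with 10,000 permutations
#' and no permuted statistic reaching the observed accuracy it equals 1e-4.
#'
#' @inheritParams nested_cv
#' @param n_permutations Number of label permutations (>= 1; the reference
#'   protocol uses 10,000).
#' @param seed Seed for the permutation draws (independent of the CV seed
#'   inside `config`).
#' @return An object of class `permutation_result`: `observed_stat` (pooled
#'   CV accuracy on true labels), `perm_stats`, `n_as_extreme`, `p_value`,
#'   `n_permutations`.
#' @export
permutation_test <- function(X, y, spec, config = cv_config(),
                             n_permutations = 10000L, seed = 1L) {
  if (n_permutations < 1L) stopf("n_permutations must be >= 1")
  if (inherits(y, "subject_labels")) y <- y$diagnosis
  y <- droplevels(as.factor(y))
  observed <- nested_cv(X, y, spec, config)$accuracy
  n <- length(y)
  perm_stats <- vapply(seq_len(n_permutations), function(i) {
    y_perm <- with_seed(cv_fold_seed(seed, 0L, i), y[sample.int(n)])
    nested_cv(X, y_perm, spec, config)$accuracy
  }, numeric(1))
  b <- sum(perm_stats >= observed)
  structure(
    list(observed_stat = observed,
         perm_stats = perm_stats,
         n_permutations = as.integer(n_permutations),
         n_as_extreme = as.integer(b),
         p_value = (1 + b) / (1 + n_permutations)),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed accuracy %.4f; %d/%d permutations as extreme; p = %.4g\n",
              x$observed_stat, x$n_as_extreme, x$n_permutations, x$p_value))
  invisible(x)
}
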