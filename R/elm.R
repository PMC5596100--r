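#' Extreme learning machine: training
#'
#' Single-hidden-layer feed-forward network whose hidden layer is fixed at
#' random and never trained: input weights and biases are drawn uniformly on
#' [-1, 1] from the seeded generator, the hidden activations are
#' `H = g(X W' + b)`, and only the output weights are learned, as the
#' minimum-norm least-squares solution `beta = pinv(H) T` (SVD
#' pseudo-inverse, relative singular-value cutoff 1e-12, no ridge term).
#' Targets are one-hot in {-1, +1}, one column per class.
#'
#' The only hyperparameter is the number of hidden nodes `n_hidden`; see
#' [tune_hidden_nodes()]. Features should be scaled to [-1, 1] beforehand
#' (see [minmax_scale_fit()]); training is deterministic given
#' `(X, y, n_hidden, seed)`.
#'
#' @param X Numeric feature matrix, n x d, finite.
#' @param y Class labels of length n, coercible to a two-level factor; both
#'   classes must be present. Factor level order fixes the class encoding
#'   (ties in prediction break toward the first level).
#' @param n_hidden Number of hidden nodes (positive integer).
#' @param seed Integer seed for the random hidden layer.
#' @param activation Hidden-unit nonlinearity: logistic `"sigmoid"`
#'   (default) or `"tanh"`.
#' @return An object of class `elm_model` with elements `input_weights`
#'   (n_hidden x d), `biases`, `output_weights` (n_hidden x 2), `classes`,
#'   `activation`, `n_hidden`, `seed`.
#' @examples
#' X <- rbind(matrix(rnorm(20, -2), 10), matrix(rnorm(20, 2), 10))
#' y <- rep(c("control", "patient"), each = 10)
#' fit <- elm_train(X, y, n_hidden = 10, seed = 1)
#' mean(elm_predict(fit, X) == y)
#' @export
elm_train <- function(X, y, n_hidden, seed, activation = c("sigmoid", "tanh")) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  if (any(!is.finite(X))) stopf("X contains non-finite values")
  if (length(n_hidden) != 1L || n_hidden < 1L) stopf("n_hidden must be a positive integer")
  n_hidden <- as.integer(n_hidden)
  y <- as.factor(y)
  y <- droplevels(y)
  if (nlevels(y) != 2L) {
    stopf("y must contain exactly two classes, got %d (%s)", nlevels(y),
          paste(levels(y), collapse = ", "))
  }
  if (length(y) != nrow(X)) stopf("length(y) != nrow(X)")
  d <- ncol(X)
  rng <- with_seed(seed, {
    list(w = matrix(stats::runif(n_hidden * d, -1, 1), n_hidden, d),
         b = stats::runif(n_hidden, -1, 1))
  })
  H <- elm_hidden(X, rng$w, rng$b, activation)
  targets <- matrix(-1, nrow(X), 2L)
  targets[cbind(seq_along(y), as.integer(y))] <- 1
  beta <- pseudo_inverse(H) %*% targets
  structure(
    list(n_hidden = n_hidden, input_weights = rng$w, biases = rng$b,
         output_weights = beta, activation = activation,
         classes = levels(y), seed = as.integer(seed)),
    class = "elm_model"
  )
}

# Hidden-layer activations H = g(X W' + b).
elm_hidden <- function(X, w, b, activation) {
  a <- tcrossprod(X, w)
  a <- sweep(a, 2L, b, "+")
  switch(activation,
         sigmoid = 1 / (1 + exp(-a)),
         tanh = tanh(a))
}

#' Extreme learning machine: output-node scores
#'
#' @param model An [elm_train()] fit.
#' @param X Feature matrix with the training dimensionality.
#' @return n x 2 matrix of output-node scores (columns named by class).
#' @export
elm_scores <- function(model, X) {
  stopifnot(inherits(model, "elm_model"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$input_weights)) {
    stopf("X has %d columns but the model was trained on %d features",
          ncol(X), ncol(model$input_weights))
  }
  H <- elm_hidden(X, model$input_weights, model$biases, model$activation)
  s <- H %*% model$output_weights
  colnames(s) <- model$classes
  s
}

#' Extreme learning machine: prediction
#'
#' Predicts the class of the maximal output-node score; exact ties break
#' toward the first class of the model's class encoding.
#'
#' @inheritParams elm_scores
#' @return Factor of predicted labels with the model's class levels.
#' @export
elm_predict <- function(model, X) {
  s <- elm_scores(model, X)
  # max.col(ties.method = "first") would be fine, but be explicit about the
  # documented tie rule under floating-point equality
  pred <- ifelse(s[, 2L] > s[, 1L], 2L, 1L)
  factor(model$classes[pred], levels = model$classes)
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d hidden nodes (%s), %d input features, classes: %s\n",
              x$n_hidden, x$activation, ncol(x$input_weights),
              paste(x$classes, collapse = " vs ")))
  invisible(x)
}

#' Hidden-node search for the extreme learning machine
#'
#' Scans a candidate range of hidden-node counts (the reference design uses
#' 90:220) and evaluates each by stratified k-fold cross-validation on the
#' supplied training data, returning the first maximizer of mean accuracy
#' together with the full accuracy profile. Candidates at or above the inner
#' training-set size trigger a warning (the interpolation regime) but are
#' still evaluated.
#'
#' @param X Training feature matrix (already scaled).
#' @param y Training labels (two classes).
#' @param search_range Integer vector of candidate hidden-node counts.
#' @param n_folds Inner stratified folds (default 5; reduced automatically
#'   if a class is smaller than the fold count).
#' @param seed Integer seed controlling fold assignment and the per-fit
#'   random hidden layers.
#' @param activation Passed to [elm_train()].
#' @return List with `n_hidden` (selected count) and `profile` (data frame
#'   of candidate vs mean inner-CV accuracy).
#' @export
tune_hidden_nodes <- function(X, y, search_range, n_folds = 5L, seed = 1L,
                              activation = "sigmoid") {
  if (length(search_range) < 1L) stopf("search_range must be nonempty")
  search_range <- as.integer(search_range)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n_folds <- min(as.integer(n_folds), min(table(y)))
  if (n_folds < 2L) {
    # too little data for an inner split: rank candidates by training fit
    acc <- vapply(search_range, function(nh) {
      fit <- elm_train(X, y, nh, seed = cv_fold_seed(seed, 1L, 1L),
                       activation = activation)
      mean(elm_predict(fit, X) == y)
    }, numeric(1))
    return(list(n_hidden = search_range[which.max(acc)],
                profile = data.frame(n_hidden = search_range, accuracy = acc)))
  }
  folds <- stratified_folds(y, n_folds, seed = seed)
  max_train <- nrow(X) - min(table(folds))
  if (any(search_range >= max_train)) {
    warning(sprintf(
      "candidate hidden-node count >= inner training size (%d); fits are in the interpolation regime",
      max_train), call. = FALSE)
  }
  # precompute fold splits once; every candidate sees identical splits
  acc <- vapply(search_range, function(nh) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- elm_train(X[tr, , drop = FALSE], y[tr], nh,
                       seed = cv_fold_seed(seed, 1L, f), activation = activation)
      correct <- correct + sum(elm_predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / nrow(X)
  }, numeric(1))
  list(n_hidden = search_range[which.max(acc)],
       profile = data.frame(n_hidden = search_range, accuracy = acc))
}

#' Classifier specification for cross-validation
#'
#' Bundles the extreme learning machine's settings so evaluation routines
#' can train and tune it uniformly. If `search_range` is `NULL`, the fixed
#' `n_hidden` is used with no tuning; otherwise the hidden-node count is
#' selected per training partition according to the evaluation routine's
#' tuning mode.
#'
#' @param n_hidden Fixed hidden-node count (used when `search_range` is
#'   `NULL`; default 100).
#' @param search_range Optional integer vector of candidates for the
#'   hidden-node search (the reference design uses `90:220`).
#' @param activation `"sigmoid"` or `"tanh"`.
#' @return An object of class `elm_spec`.
#' @export
elm_spec <- function(n_hidden = 100L, search_range = NULL,
                     activation = c("sigmoid", "tanh")) {
  activation <- match.arg(activation)
  structure(list(n_hidden = as.integer(n_hidden),
                 search_range = if (!is.null(search_range)) as.integer(search_range),
                 activation = activation),
            class = "elm_spec")
}

#' Serialize an ELM model to a portable JSON file
#'
#' All matrices and metadata are written as plain JSON so a fitted model can
#' be stored or exchanged without binary formats.
#'
#' @param model An [elm_train()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_elm <- function(model, path) {
  stopifnot(inherits(model, "elm_model"))
  obj <- list(n_hidden = model$n_hidden,
              input_weights = model$input_weights,
              biases = model$biases,
              output_weights = model$output_weights,
              activation = model$activation,
              classes = model$classes,
              seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a serialized ELM model
#'
#' @param path Path written by [save_elm()].
#' @return An `elm_model`.
#' @export
load_elm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x, nr) {
    if (is.matrix(x)) x else matrix(as.numeric(x), nrow = nr)
  }
  structure(
    list(n_hidden = as.integer(obj$n_hidden),
         input_weights = as_mat(obj$input_weights, obj$n_hidden),
         biases = as.numeric(obj$biases),
         output_weights = as_mat(obj$output_weights, obj$n_hidden),
         activation = obj$activation,
         classes = obj$classes,
         seed = as.integer(obj$seed)),
    class = "elm_model"
  )
}
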