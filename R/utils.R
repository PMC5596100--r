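# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's
#' `.Random.seed` afterwards, so package functions never disturb the global
#' RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Deterministic child seed for a cross-validation fold
#'
#' Derives the seed used to draw the random hidden layer (and any other
#' classifier randomness) for repeat `r`, fold `f` of a cross-validation run
#' with master seed `seed`. Exposed so an external loop can reproduce
#' [nested_cv()] fold by fold.
#'
#' @param seed Master seed of the cross-validation run.
#' @param r Repeat index (1-based).
#' @param f Fold index (1-based).
#' @return A single integer below 2^31.
#' @export
cv_fold_seed <- function(seed, r, f) {
  as.integer((as.numeric(seed) + 100003 * r + 1009 * f) %% .Machine$integer.max)
}

#' Deterministic child seed for a cross-validation repeat
#'
#' Seed used by [stratified_folds()] for repeat `r` of a run with master
#' seed `seed`.
#'
#' @inheritParams cv_fold_seed
#' @return A single integer below 2^31.
#' @export
cv_repeat_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + 7919 * (r - 1)) %% .Machine$integer.max)
}

# Moore-Penrose pseudo-inverse via SVD with a relative singular-value cutoff.
pseudo_inverse <- function(m, tol = 1e-12) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(m), nrow(m)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
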