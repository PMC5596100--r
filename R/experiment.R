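# End-to-end orchestration: per-measure accuracies -> fusion weights ->
# fused classification under nested CV, with optional permutation testing,
# on synthetic or user-supplied feature tables.

#' Published per-measure reference accuracies
#'
#' The 12 per-measure extreme-learning-machine test accuracies published
#' for the reference schizophrenia-vs-control study design (COBRE-derived
#' structural and functional feature tables, nested 10-by-10-fold CV).
#' These are the worked example of the weighting rule: feeding them to
#' [compute_weights()] reproduces the published weight table to 4 decimals.
#'
#' @return Named numeric vector of 12 accuracies (by measure).
#' @examples
#' compute_weights(reference_measure_accuracies())
#' @export
reference_measure_accuracies <- function() {
  path <- system.file("extdata", "cobre_elm_measure_accuracies.csv",
                      package = "elmfusion", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  stats::setNames(df$elm_test_accuracy, df$measure)
}

#' Run configuration for a full experiment
#'
#' @param spec A [synth_spec()] describing the dataset to simulate, or NULL
#'   when `dataset` is given to [run_experiment()] directly.
#' @param classifier An [elm_spec()] (default: fixed 100 hidden nodes; pass
#'   `elm_spec(search_range = 90:220)` for the full hidden-node search).
#' @param cv A [cv_config()] for the outer evaluation.
#' @param methods Fusion methods to evaluate (subset of simple / weighted /
#'   hybrid).
#' @param weight_mode `"whole_dataset"` (default: weights computed once, as
#'   published weight tables are) or `"within_fold"` (leakage-free; see
#'   [fused_nested_cv()]).
#' @param n_permutations Permutations for the significance test of each
#'   fused model (0 = skip; the reference protocol uses 10,000).
#' @param seed Master seed; stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spec = table2_spec(), classifier = elm_spec(),
                       cv = cv_config(),
                       methods = c("simple", "weighted", "hybrid"),
                       weight_mode = c("whole_dataset", "within_fold"),
                       n_permutations = 0L, seed = 1L) {
  weight_mode <- match.arg(weight_mode)
  methods <- match.arg(methods, c("simple", "weighted", "hybrid"),
                       several.ok = TRUE)
  structure(list(spec = spec, classifier = classifier, cv = cv,
                 methods = methods, weight_mode = weight_mode,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full fusion experiment grid
#'
#' Reproduces the experiment structure of the fusion framework on a
#' dataset: (1) per-measure nested-CV accuracies, (2) fusion weights from
#' those accuracies, (3) fused classification under nested CV for each
#' requested concatenation method, (4) optionally a permutation test per
#' fused model. All randomness derives from `config$seed`; rerunning with
#' the same config reproduces the report exactly.
#'
#' @param config A [run_config()].
#' @param dataset Optional [assemble_dataset()] result; by default the
#'   dataset is generated from `config$spec` with the master seed.
#' @return An object of class `experiment_report`: `per_measure` (data
#'   frame of accuracy per weight key), `weights` (data frame with rank,
#'   measure, accuracy, weight), `fused` (data frame of metrics per fusion
#'   method, including permutation p-values when requested), `seed`, and
#'   the `config`.
#' @export
run_experiment <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(dataset)) {
    if (is.null(config$spec)) stopf("config has no synth spec and no dataset was given")
    dataset <- generate_dataset(config$spec, seed = config$seed)
  }
  cv_meas <- config$cv
  cv_meas$seed <- config$seed + 1L
  acc <- per_measure_accuracy(dataset, config$classifier, cv_meas)
  weights <- compute_weights(acc)
  ord <- order(-weights$weights)
  weights_df <- data.frame(rank = seq_along(ord),
                           measure = names(weights$weights)[ord],
                           accuracy = unname(weights$accuracy[ord]),
                           weight = unname(weights$weights[ord]),
                           row.names = NULL)
  fused_rows <- lapply(config$methods, function(method) {
    res <- fused_nested_cv(dataset, method = method, spec = config$classifier,
                           config = config$cv, weight_mode = config$weight_mode)
    met <- stats::setNames(res$cv$metrics$mean, res$cv$metrics$metric)
    p_value <- NA_real_
    if (config$n_permutations > 0L) {
      # permute against the fused design exactly as evaluated
      weights_obj <- if (method == "simple") NULL else
        if (is.data.frame(res$weights)) NULL else res$weights
      X <- if (method == "simple" || config$weight_mode == "whole_dataset") {
        fuse_blocks(scale_dataset(dataset)$measures, dataset$labels, method,
                    weights_obj)
      } else NULL
      if (!is.null(X)) {
        cfg <- config$cv
        cfg$scaling_mode <- "none"
        p_value <- permutation_test(X, dataset$labels, config$classifier, cfg,
                                    n_permutations = config$n_permutations,
                                    seed = config$seed + 2L)$p_value
      }
    }
    data.frame(method = method,
               train_accuracy = res$cv$train_accuracy,
               test_accuracy = res$cv$accuracy,
               sensitivity = met[["sensitivity"]],
               specificity = met[["specificity"]],
               f1 = met[["f1"]],
               ppv = met[["ppv"]],
               npv = met[["npv"]],
               p_value = p_value,
               row.names = NULL)
  })
  per_measure <- data.frame(measure = names(acc$accuracy),
                            accuracy = unname(acc$accuracy),
                            row.names = NULL)
  structure(list(per_measure = per_measure,
                 weights = weights_df,
                 fused = do.call(rbind, fused_rows),
                 weight_mode = config$weight_mode,
                 seed = config$seed,
                 config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> seed %d, weight mode '%s'\n",
              x$seed, x$weight_mode))
  cat("\nPer-measure nested-CV accuracy and fusion weight:\n")
  print(transform(x$weights, accuracy = round(accuracy, 4),
                  weight = round(weight, 4)), row.names = FALSE)
  cat("\nFused models:\n")
  fused <- x$fused
  num <- vapply(fused, is.numeric, logical(1))
  fused[num] <- lapply(fused[num], round, 4)
  print(fused, row.names = FALSE)
  invisible(x)
}

#' Serialize an experiment report to JSON
#'
#' Writes the full report (per-measure accuracies, weight table, fused
#' metrics, seed) as machine-readable JSON.
#'
#' @param report An [run_experiment()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  jsonlite::write_json(
    list(seed = report$seed,
         weight_mode = report$weight_mode,
         per_measure = report$per_measure,
         weights = report$weights,
         fused = report$fused),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
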