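# Seeded generator of two-group multimodal feature tables with the
# statistical structure the fusion method assumes: per-measure Gaussian
# feature blocks with a controllable class separation, so per-measure
# accuracies differ and the weighting scheme is exercised end to end
# without any imaging data.

#' Construct a synthetic-dataset specification
#'
#' Describes a balanced (or unbalanced) two-group multimodal dataset
#' measure by measure. Within a measure, an `frac_informative` fraction of
#' columns carries a class-mean separation of `effect_size` noise standard
#' deviations and is equicorrelated at `rho`; the remaining columns are
#' pure noise. Effect sizes in noise-SD units make expected separability
#' analytic (per-feature AUC = pnorm(effect_size / sqrt(2))).
#'
#' @param measures Data frame with columns `label`, `group` (cortical /
#'   subcortical / wholebrain / gica), `n_features`, `effect_size`
#'   (delta >= 0), `frac_informative` (in (0, 1]), `rho` (in [0, 1)), and
#'   optionally `weight_key` (defaults to `label`).
#' @param n_per_group Integer pair, subjects per class
#'   `c(control, patient)`; default `c(72, 72)`.
#' @param noise_scale Positive noise standard deviation (default 1).
#' @return An object of class `synth_spec`.
#' @seealso [table2_spec()], [generate_dataset()]
#' @export
synth_spec <- function(measures, n_per_group = c(72L, 72L), noise_scale = 1) {
  measures <- as.data.frame(measures)
  need <- c("label", "group", "n_features", "effect_size",
            "frac_informative", "rho")
  missing_cols <- setdiff(need, colnames(measures))
  if (length(missing_cols)) {
    stopf("measure table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!"weight_key" %in% colnames(measures)) measures$weight_key <- measures$label
  if (any(measures$n_features < 1)) stopf("feature counts must be positive")
  if (any(measures$effect_size < 0)) stopf("effect sizes must be >= 0")
  if (any(measures$frac_informative <= 0 | measures$frac_informative > 1)) {
    stopf("frac_informative must lie in (0, 1]")
  }
  if (any(measures$rho < 0 | measures$rho >= 1)) stopf("rho must lie in [0, 1)")
  if (anyDuplicated(measures$label)) stopf("duplicated measure labels")
  if (length(n_per_group) != 2L || any(n_per_group < 1)) {
    stopf("n_per_group must be two positive counts")
  }
  if (noise_scale <= 0) stopf("noise_scale must be positive")
  structure(list(measures = measures,
                 n_per_group = as.integer(n_per_group),
                 noise_scale = as.numeric(noise_scale)),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("<synth_spec> %d + %d subjects, %d measures, %d features total\n",
              x$n_per_group[1], x$n_per_group[2], nrow(x$measures),
              sum(x$measures$n_features)))
  print(x$measures, row.names = FALSE)
  invisible(x)
}

#' Default specification: the reference study-design geometry
#'
#' The 14 feature blocks of the reference two-group design (72 + 72
#' subjects): seven cortical blocks (449 features), three subcortical
#' blocks (76), three whole-brain blocks (52, two of which share their
#' fusion weight with the like-named subcortical measures), and one ICA
#' connectivity block (171 = 19 components' upper-triangle correlations) —
#' 748 features total under 12 distinct fusion weights.
#'
#' Effect sizes are fixed, plausible defaults chosen so that the ICA
#' connectivity block is the most discriminative measure and per-measure
#' accuracies spread over a visible range, exercising the weighting scheme.
#'
#' @return A [synth_spec()].
#' @export
table2_spec <- function() {
  measures <- data.frame(
    label = c("Thickness", "Thickness STD", "Surface Area", "Volume",
              "Curvature", "WM", "Cortical GCOR",
              "SC Volume", "SC Intensity", "SC GCOR",
              "Overall Volume", "WB Intensity", "WB GCOR",
              "Group ICA"),
    group = c(rep("cortical", 7L), rep("subcortical", 3L),
              rep("wholebrain", 3L), "gica"),
    weight_key = c("Thickness", "Thickness STD", "Surface Area", "Volume",
                   "Curvature", "WM", "Cortical GCOR",
                   "SC Volume", "SC Intensity", "SC GCOR",
                   "Overall Volume", "SC Intensity", "SC GCOR",
                   "Group ICA"),
    n_features = c(64L, 62L, 64L, 62L, 62L, 68L, 67L,
                   26L, 26L, 24L,
                   27L, 14L, 11L,
                   171L),
    effect_size = c(0.80, 0.70, 0.50, 0.70, 0.90, 0.60, 0.70,
                    0.60, 0.60, 0.80,
                    0.75, 0.60, 0.80,
                    1.00),
    frac_informative = 0.3,
    rho = 0.2)
  synth_spec(measures, n_per_group = c(72L, 72L), noise_scale = 1)
}

#' Generate a synthetic multimodal dataset
#'
#' Draws class-conditional Gaussian feature blocks per the spec:
#' informative columns (the first `round(frac_informative * n_features)`,
#' at least one) have class means separated by `effect_size * noise_scale`
#' (placed at -delta/2 and +delta/2 around zero, the patient group higher)
#' and share an equicorrelation `rho` through a per-subject latent factor;
#' the remaining columns are independent noise. One label vector is shared
#' by all measures. Deterministic given the seed.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @return A [assemble_dataset()] result with subjects `s001, s002, ...`
#'   (controls first) and diagnosis levels `control` / `patient`.
#' @export
generate_dataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  n0 <- spec$n_per_group[1L]; n1 <- spec$n_per_group[2L]
  n <- n0 + n1
  ids <- sprintf("s%03d", seq_len(n))
  diagnosis <- rep(c("control", "patient"), c(n0, n1))
  labels <- subject_labels(ids, diagnosis)
  sigma <- spec$noise_scale
  measures <- with_seed(seed, {
    lapply(seq_len(nrow(spec$measures)), function(i) {
      row <- spec$measures[i, ]
      p <- row$n_features
      n_inf <- max(1L, as.integer(round(row$frac_informative * p)))
      n_inf <- min(n_inf, p)
      X <- matrix(stats::rnorm(n * p), n, p) * sigma
      if (row$rho > 0 && n_inf > 1L) {
        latent <- stats::rnorm(n)
        X[, seq_len(n_inf)] <- sigma * (
          sqrt(row$rho) * latent +
            sqrt(1 - row$rho) * (X[, seq_len(n_inf), drop = FALSE] / sigma))
      }
      if (row$effect_size > 0) {
        shift <- row$effect_size * sigma / 2
        X[, seq_len(n_inf)] <- X[, seq_len(n_inf), drop = FALSE] +
          ifelse(diagnosis == "patient", shift, -shift)
      }
      feature_measure(X, label = row$label, group = row$group,
                      weight_key = row$weight_key,
                      subject_ids = ids,
                      feature_names = sprintf("%s_f%03d", gsub("\\s+", "_", row$label),
                                              seq_len(p)))
    })
  })
  assemble_dataset(measures, labels)
}

#' Write a synthetic dataset to a directory of delimited files
#'
#' One CSV per measure plus `labels.csv` and a JSON manifest
#' (`manifest.json`) listing label, group, weight key and file per measure —
#' the on-disk interchange layout that [load_measure()] / [load_labels()]
#' read back.
#'
#' @param dataset A [assemble_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(dataset$measures, function(m) {
    file <- paste0(gsub("[^A-Za-z0-9]+", "_", tolower(m$label)), ".csv")
    save_measure(m, file.path(dir, file))
    list(label = m$label, group = m$group, weight_key = m$weight_key,
         file = file)
  })
  save_labels(dataset$labels, file.path(dir, "labels.csv"))
  jsonlite::write_json(list(labels = "labels.csv", measures = unname(manifest)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a dataset from a manifest directory
#'
#' Reads the layout written by [save_dataset()].
#'
#' @param dir Directory containing `manifest.json`.
#' @return A [assemble_dataset()] result.
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  labels <- load_labels(file.path(dir, manifest$labels))
  measures <- lapply(manifest$measures, function(m) {
    load_measure(file.path(dir, m$file), label = m$label, group = m$group,
                 weight_key = m$weight_key %||% m$label)
  })
  assemble_dataset(measures, labels)
}
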