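# Small in-code fixtures shared across test files.

# Two well-separated Gaussian clusters: n_per subjects per class, d features,
# class means at -delta/2 and +delta/2.
separable_data <- function(n_per = 10, d = 4, delta = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * d), 2 * n_per, d)
  y <- rep(c("control", "patient"), each = n_per)
  X <- X + ifelse(y == "patient", delta / 2, -delta / 2)
  list(X = X, y = factor(y, levels = c("control", "patient")))
}

# A minimal multimodal dataset covering all four anatomical groups.
toy_dataset <- function(n_per = 15, seed = 1,
                        effects = c(cortA = 0, cortB = 0, scA = 0, scB = 0,
                                    ica = 0),
                        n_features = c(cortA = 8, cortB = 8, scA = 6, scB = 6,
                                       ica = 10)) {
  measures <- data.frame(
    label = c("cortA", "cortB", "scA", "scB", "ica"),
    group = c("cortical", "cortical", "subcortical", "subcortical", "gica"),
    n_features = unname(n_features[c("cortA", "cortB", "scA", "scB", "ica")]),
    effect_size = unname(effects[c("cortA", "cortB", "scA", "scB", "ica")]),
    frac_informative = 0.5,
    rho = 0.2)
  generate_dataset(synth_spec(measures, n_per_group = c(n_per, n_per)),
                   seed = seed)
}

# Hand-built feature measure from a plain matrix.
mk_measure <- function(values, label, group = "cortical", ids = NULL,
                       weight_key = label) {
  ids <- ids %||% paste0("s", seq_len(nrow(values)))
  feature_measure(as.matrix(values), label = label, group = group,
                  weight_key = weight_key, subject_ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
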