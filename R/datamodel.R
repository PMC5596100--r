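#' Construct a feature measure
#'
#' A feature measure is one homogeneous block of per-subject features — for
#' example cortical thickness per parcel, subcortical segment volumes, or a
#' vectorized ICA connectivity matrix — treated as a unit by the fusion
#' scheme. Rows are subjects, columns are features.
#'
#' @param values Numeric matrix, subjects x features. All entries must be
#'   finite; missing values are a hard error (quality control of upstream
#'   feature extraction is out of scope here).
#' @param label Measure label, unique within a dataset (e.g. `"Thickness"`,
#'   `"Group ICA"`).
#' @param group Anatomical group tag: `"cortical"`, `"subcortical"`,
#'   `"wholebrain"` or `"gica"`. Drives block membership in
#'   [hybrid_weighted_concat()].
#' @param weight_key Key under which this measure shares a fusion weight.
#'   Defaults to `label`. Whole-brain intensity and whole-brain global
#'   connectivity blocks reuse the weight of the like-named subcortical
#'   measure, so several measures may share one key.
#' @param subject_ids Character vector of subject identifiers, one per row.
#'   Defaults to the matrix rownames.
#' @param feature_names Character vector of feature names, one per column.
#'   Defaults to the matrix colnames.
#' @return An object of class `feature_measure`.
#' @seealso [load_measure()], [assemble_dataset()]
#' @export
feature_measure <- function(values, label, group,
                            weight_key = label,
                            subject_ids = rownames(values),
                            feature_names = colnames(values)) {
  group <- match.arg(group, c("cortical", "subcortical", "wholebrain", "gica"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(subject_ids)) {
    stopf("measure '%s': subject ids are required (rownames or subject_ids)", label)
  }
  if (is.null(feature_names)) {
    feature_names <- paste0(label, "_f", seq_len(ncol(values)))
  }
  subject_ids <- as.character(subject_ids)
  feature_names <- as.character(feature_names)
  if (nrow(values) != length(subject_ids)) {
    stopf("measure '%s': %d rows but %d subject ids", label,
          nrow(values), length(subject_ids))
  }
  if (ncol(values) != length(feature_names)) {
    stopf("measure '%s': %d columns but %d feature names", label,
          ncol(values), length(feature_names))
  }
  if (anyDuplicated(subject_ids)) {
    stopf("measure '%s': duplicated subject id(s): %s", label,
          paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("measure '%s': non-finite value at row %d ('%s'), column %d ('%s')",
          label, bad[1, 1], subject_ids[bad[1, 1]],
          bad[1, 2], feature_names[bad[1, 2]])
  }
  dimnames(values) <- list(subject_ids, feature_names)
  structure(
    list(label = as.character(label), group = group,
         weight_key = as.character(weight_key),
         values = values,
         subject_ids = subject_ids, feature_names = feature_names),
    class = "feature_measure"
  )
}

#' @export
print.feature_measure <- function(x, ...) {
  cat(sprintf("<feature_measure> %s [%s, weight key '%s']: %d subjects x %d features\n",
              x$label, x$group, x$weight_key,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct subject class labels
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param diagnosis Per-subject class, a vector coercible to character with
#'   exactly two distinct values. Both classes must be present.
#' @param class_levels Ordered class pair `c(negative, positive)`. The second
#'   level is the positive class for confusion-matrix bookkeeping (patients,
#'   in a case--control design). Defaults to `c("control", "patient")` when
#'   those are the observed values, otherwise to the sorted observed values.
#' @return An object of class `subject_labels`.
#' @export
subject_labels <- function(subject_ids, diagnosis, class_levels = NULL) {
  subject_ids <- as.character(subject_ids)
  diagnosis <- as.character(diagnosis)
  if (length(subject_ids) != length(diagnosis)) {
    stopf("%d subject ids but %d diagnoses", length(subject_ids), length(diagnosis))
  }
  if (anyDuplicated(subject_ids)) {
    stopf("duplicated subject id(s): %s",
          paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  }
  obs <- unique(diagnosis)
  if (is.null(class_levels)) {
    class_levels <- if (setequal(obs, c("control", "patient"))) {
      c("control", "patient")
    } else sort(obs)
  }
  if (length(class_levels) != 2L || !setequal(obs, class_levels)) {
    stopf("exactly two classes are required and both must be present; observed: %s",
          paste(obs, collapse = ", "))
  }
  structure(
    list(subject_ids = subject_ids,
         diagnosis = factor(diagnosis, levels = class_levels)),
    class = "subject_labels"
  )
}

#' @export
print.subject_labels <- function(x, ...) {
  tab <- table(x$diagnosis)
  cat(sprintf("<subject_labels> %d subjects (%s)\n", length(x$subject_ids),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Assemble measures and labels into a multimodal dataset
#'
#' Validates that every measure covers exactly the labeled subjects and
#' canonicalizes row order to the label file's subject order, which removes
#' silent row misalignment between modalities — the classic fusion bug.
#'
#' @param measures A list of [feature_measure()] objects with unique labels.
#' @param labels A [subject_labels()] object covering all subjects.
#' @return An object of class `multimodal_dataset`.
#' @export
assemble_dataset <- function(measures, labels) {
  if (inherits(measures, "feature_measure")) measures <- list(measures)
  if (length(measures) < 1L) stopf("at least one measure is required")
  stopifnot(inherits(labels, "subject_labels"))
  labs <- vapply(measures, function(m) m$label, character(1))
  if (anyDuplicated(labs)) {
    stopf("duplicated measure label(s): %s",
          paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  ref <- labels$subject_ids
  measures <- lapply(measures, function(m) {
    missing_ids <- setdiff(ref, m$subject_ids)
    extra_ids <- setdiff(m$subject_ids, ref)
    if (length(missing_ids) || length(extra_ids)) {
      stopf("measure '%s': subject ids do not match labels%s%s", m$label,
            if (length(missing_ids)) paste0("; missing: ",
              paste(missing_ids, collapse = ", ")) else "",
            if (length(extra_ids)) paste0("; unlabeled: ",
              paste(extra_ids, collapse = ", ")) else "")
    }
    idx <- match(ref, m$subject_ids)
    m$values <- m$values[idx, , drop = FALSE]
    m$subject_ids <- ref
    rownames(m$values) <- ref
    m
  })
  names(measures) <- labs
  structure(list(measures = measures, labels = labels),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat(sprintf("<multimodal_dataset> %d subjects, %d measures, %d features total\n",
              length(x$labels$subject_ids), length(x$measures),
              total_feature_count(x)))
  for (m in x$measures) {
    cat(sprintf("  %-16s %-11s %4d features (weight key '%s')\n",
                m$label, m$group, ncol(m$values), m$weight_key))
  }
  invisible(x)
}

#' Total feature count of a dataset
#'
#' Sum of the per-measure column counts. For the default study-design
#' geometry (see [table2_spec()]) this is 748.
#'
#' @param dataset A [assemble_dataset()] result.
#' @return Non-negative integer.
#' @export
total_feature_count <- function(dataset) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  sum(vapply(dataset$measures, function(m) ncol(m$values), integer(1)))
}

#' Read a feature table from delimited text
#'
#' Expects a header row of feature names and a first column of subject ids.
#' Row order of the file is preserved.
#'
#' @inheritParams feature_measure
#' @param path Path to a CSV (or TSV, with `sep = "\t"`) feature table.
#' @param sep Field separator; comma by default.
#' @return A [feature_measure()].
#' @export
load_measure <- function(path, label, group, weight_key = label, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 2L) stopf("'%s': expected a subject-id column plus >=1 feature column", path)
  ids <- df[[1L]]
  feat <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(feat), nrow(feat), ncol(feat),
                                 dimnames = dimnames(feat)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("'%s': non-numeric or missing cell '%s' at data row %d (subject '%s'), column '%s'",
          path, feat[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
          colnames(feat)[bad[1, 2]])
  }
  feature_measure(num, label = label, group = group, weight_key = weight_key,
                  subject_ids = ids, feature_names = colnames(feat))
}

#' Write a feature table to delimited text
#'
#' Inverse of [load_measure()]: header row of feature names, first column
#' `subject_id`. Values survive a save/load round trip to the precision of
#' the decimal representation (15 significant digits).
#'
#' @param measure A [feature_measure()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
save_measure <- function(measure, path, sep = ",") {
  stopifnot(inherits(measure, "feature_measure"))
  df <- data.frame(subject_id = measure$subject_ids,
                   format(measure$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("subject_id", measure$feature_names)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read subject labels from delimited text
#'
#' Expects columns `subject_id` and `diagnosis`.
#'
#' @param path Path to the labels CSV.
#' @param sep Field separator.
#' @inheritParams subject_labels
#' @return A [subject_labels()].
#' @export
load_labels <- function(path, sep = ",", class_levels = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", comment.char = "")
  need <- c("subject_id", "diagnosis")
  if (!all(need %in% colnames(df))) {
    stopf("'%s': expected columns %s", path, paste(need, collapse = ", "))
  }
  subject_labels(df$subject_id, df$diagnosis, class_levels = class_levels)
}

#' Write subject labels to delimited text
#'
#' @param labels A [subject_labels()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
save_labels <- function(labels, path, sep = ",") {
  stopifnot(inherits(labels, "subject_labels"))
  utils::write.table(
    data.frame(subject_id = labels$subject_ids,
               diagnosis = as.character(labels$diagnosis)),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
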