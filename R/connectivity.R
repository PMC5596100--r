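# Post-preprocessing functional-connectivity feature math. Operates on
# plain delimited matrices (voxel id column + timepoint columns); no
# neuroimaging binary formats.

#' Construct a voxel x time series volume
#'
#' @param values Numeric matrix, M voxels x T timepoints (T >= 3).
#' @param voxel_ids Voxel identifiers, one per row; defaults to rownames or
#'   `v1..vM`.
#' @return An object of class `time_series_volume`.
#' @export
time_series_volume <- function(values, voxel_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 3L) stopf("need at least 3 timepoints, got %d", ncol(values))
  if (is.null(voxel_ids)) voxel_ids <- paste0("v", seq_len(nrow(values)))
  voxel_ids <- as.character(voxel_ids)
  if (length(voxel_ids) != nrow(values)) {
    stopf("%d voxel ids for %d rows", length(voxel_ids), nrow(values))
  }
  if (anyDuplicated(voxel_ids)) stopf("duplicated voxel ids")
  if (any(!is.finite(values))) stopf("time series contain non-finite values")
  rownames(values) <- voxel_ids
  structure(list(values = values, voxel_ids = voxel_ids),
            class = "time_series_volume")
}

#' Demean and scale voxel time series to unit Euclidean norm
#'
#' Each voxel's series is centered and divided by its Euclidean norm, the
#' scaling under which pairwise Pearson correlations become plain dot
#' products. Constant series (zero variance) are an error because their
#' correlation is undefined.
#'
#' @param ts A [time_series_volume()].
#' @return A `time_series_volume` whose rows all have zero mean and unit
#'   norm. Idempotent.
#' @export
unit_normalize <- function(ts) {
  stopifnot(inherits(ts, "time_series_volume"))
  v <- ts$values - rowMeans(ts$values)
  norms <- sqrt(rowSums(v^2))
  zero <- norms < .Machine$double.eps * ncol(v)
  if (any(zero)) {
    stopf("constant time series (zero variance) at voxel(s): %s",
          paste(ts$voxel_ids[zero], collapse = ", "))
  }
  ts$values <- v / norms
  ts
}

#' Per-voxel global-connectivity map
#'
#' The value at voxel i is the mean Pearson correlation of voxel i's time
#' series with every voxel in the volume. Computed with the unit-norm trick:
#' after [unit_normalize()], r(i, j) is the dot product of rows i and j, so
#' the per-voxel mean correlation is `U %*% colMeans(U)` — no M x M
#' correlation matrix is formed. The mean includes the voxel's own r = 1
#' term; convert to the self-exclusive mean via `(M * v - 1) / (M - 1)`.
#'
#' @param ts A [time_series_volume()] with >= 2 voxels.
#' @return An object of class `connectivity_map` on the `r` scale.
#' @export
voxelwise_global_connectivity <- function(ts) {
  stopifnot(inherits(ts, "time_series_volume"))
  if (nrow(ts$values) < 2L) stopf("need at least 2 voxels")
  u <- unit_normalize(ts)$values
  ubar <- colMeans(u)
  vals <- drop(u %*% ubar)
  # guard against round-off pushing means beyond [-1, 1]
  vals <- pmin(1, pmax(-1, vals))
  connectivity_map(vals, voxel_ids = ts$voxel_ids, scale = "r")
}

#' Construct a per-voxel connectivity map
#'
#' @param values Named or plain numeric vector of per-voxel connectivity
#'   values (mean correlation, or Fisher z).
#' @param voxel_ids Voxel identifiers.
#' @param scale `"r"` (correlation) or `"z"` (Fisher-transformed).
#' @return An object of class `connectivity_map`.
#' @export
connectivity_map <- function(values, voxel_ids = names(values), scale = c("r", "z")) {
  scale <- match.arg(scale)
  values <- as.numeric(values)
  if (is.null(voxel_ids)) voxel_ids <- paste0("v", seq_along(values))
  if (length(voxel_ids) != length(values)) stopf("voxel ids / values length mismatch")
  if (scale == "r" && any(values < -1 | values > 1)) {
    stopf("r-scale connectivity values must lie in [-1, 1]")
  }
  names(values) <- voxel_ids
  structure(list(values = values, voxel_ids = as.character(voxel_ids),
                 scale = scale),
            class = "connectivity_map")
}

#' Fisher z-transform of a correlation-scale connectivity map
#'
#' Applies z = atanh(r) per voxel to variance-stabilize correlation values.
#' Correlations with |r| >= 1 - 1e-7 are clipped to that bound first, so the
#' map stays finite (atanh diverges at +/-1).
#'
#' @param map An `r`-scale [connectivity_map()].
#' @return A `z`-scale `connectivity_map`.
#' @export
fisher_z <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  if (map$scale != "r") stopf("fisher_z requires an r-scale map (got '%s')", map$scale)
  clip <- 1 - 1e-7
  map$values <- atanh(pmin(clip, pmax(-clip, map$values)))
  map$scale <- "z"
  map
}

#' Construct a voxel-to-ROI labeling
#'
#' @param voxel_rois Named character vector mapping voxel id -> ROI id.
#' @param roi_ids ROI identifiers fixing output order; defaults to the
#'   unique ROIs in order of first appearance.
#' @return An object of class `roi_labeling`.
#' @export
roi_labeling <- function(voxel_rois, roi_ids = unique(unname(voxel_rois))) {
  if (is.null(names(voxel_rois))) stopf("voxel_rois must be named by voxel id")
  structure(list(voxel_rois = vapply(voxel_rois, as.character, character(1)),
                 roi_ids = as.character(roi_ids)),
            class = "roi_labeling")
}

#' Average a connectivity map within atlas ROIs
#'
#' Arithmetic mean of the map values over the voxels of each ROI, in the
#' labeling's ROI order. This is how voxelwise global-connectivity maps are
#' reduced to per-region features.
#'
#' @param map A [connectivity_map()] (either scale; a Fisher-z map is the
#'   usual input since the z-transform precedes ROI extraction).
#' @param labeling A [roi_labeling()]. Every labeled voxel must exist in the
#'   map and every ROI must contain at least one voxel.
#' @return Named numeric vector of per-ROI means.
#' @export
roi_average <- function(map, labeling) {
  stopifnot(inherits(map, "connectivity_map"), inherits(labeling, "roi_labeling"))
  unknown <- setdiff(names(labeling$voxel_rois), map$voxel_ids)
  if (length(unknown)) {
    stopf("labeled voxel(s) absent from map: %s", paste(unknown, collapse = ", "))
  }
  out <- vapply(labeling$roi_ids, function(roi) {
    vox <- names(labeling$voxel_rois)[labeling$voxel_rois == roi]
    if (length(vox) == 0L) stopf("ROI '%s' contains no voxels", roi)
    mean(map$values[vox])
  }, numeric(1))
  names(out) <- labeling$roi_ids
  out
}

#' Global correlation (GCOR) of a time-series volume
#'
#' Scalar summary of whole-volume connectedness: the squared Euclidean norm
#' of the voxel-averaged unit-norm time series, which equals the mean of all
#' M^2 pairwise Pearson correlations (self-correlations included) and hence
#' the mean of the [voxelwise_global_connectivity()] map. Always in [0, 1].
#'
#' `squared = FALSE` returns the unsquared norm of the averaged series
#' instead; that quantity (the square root of the default) is not the mean
#' pairwise correlation but matches a literal "l2-norm of the averaged
#' series" reading.
#'
#' @param ts A [time_series_volume()] with >= 2 voxels.
#' @param squared Return the squared norm (the mean pairwise correlation;
#'   default) or the plain norm.
#' @return A scalar in [0, 1].
#' @export
gcor <- function(ts, squared = TRUE) {
  stopifnot(inherits(ts, "time_series_volume"))
  if (nrow(ts$values) < 2L) stopf("need at least 2 voxels")
  u <- unit_normalize(ts)$values
  ubar <- colMeans(u)
  g <- sum(ubar^2)
  g <- min(1, max(0, g))
  if (squared) g else sqrt(g)
}

#' Construct ICA component time-courses
#'
#' @param values Numeric matrix, T timepoints x K components (K >= 2),
#'   e.g. the subject-specific time-courses from dual regression.
#' @param component_ids Component identifiers, one per column.
#' @return An object of class `component_timecourses`.
#' @export
component_timecourses <- function(values, component_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2L) stopf("need at least 2 components, got %d", ncol(values))
  if (nrow(values) < 3L) stopf("need at least 3 timepoints")
  if (is.null(component_ids)) component_ids <- paste0("IC", seq_len(ncol(values)))
  component_ids <- as.character(component_ids)
  if (length(component_ids) != ncol(values)) stopf("component ids / columns mismatch")
  if (any(!is.finite(values))) stopf("time-courses contain non-finite values")
  const <- apply(values, 2L, function(x) stats::var(x) < .Machine$double.eps)
  if (any(const)) {
    stopf("constant component time-course(s): %s",
          paste(component_ids[const], collapse = ", "))
  }
  colnames(values) <- component_ids
  structure(list(values = values, component_ids = component_ids),
            class = "component_timecourses")
}

#' Vectorized component-connectivity features
#'
#' Pearson correlation matrix of the K component time-courses, strict upper
#' triangle vectorized in row-major order: (1,2), (1,3), ..., (1,K),
#' (2,3), ... The result has length K(K-1)/2 — 171 features for the 19
#' retained resting-state components of the reference design.
#'
#' @param tc A [component_timecourses()].
#' @return Named numeric vector of length `K * (K - 1) / 2`.
#' @export
component_connectivity <- function(tc) {
  stopifnot(inherits(tc, "component_timecourses"))
  cm <- stats::cor(tc$values)
  k <- ncol(cm)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  # row-major order of the strict upper triangle
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  out <- cm[idx]
  names(out) <- paste0(tc$component_ids[idx[, 1L]], "-", tc$component_ids[idx[, 2L]])
  out
}
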