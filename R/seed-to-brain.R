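# Whole-brain connectivity maps of each cluster: per-run correlation of the
# cluster-mean time course with every out-of-cluster brain voxel, Fisher z,
# fixed-effects (Stouffer) group combination, and z-thresholding.

#' Per-run cluster-to-brain correlation map
#'
#' Correlates the mean time course of one cluster (average over its mask
#' voxels, after nuisance regression) with every brain voxel outside the
#' cluster, and Fisher z-transforms the result. The run and the brain matrix
#' are expected to be bandpassed consistently.
#'
#' @param run A [voxel_run] holding the mask voxels (bandpassed).
#' @param labels Integer per-voxel cluster labels for the mask.
#' @param cluster Cluster id whose map to compute.
#' @param brain Matrix of brain voxels x time (same volumes as the run),
#'   already conditioned like the run; the cluster's own voxels are assumed
#'   external to this matrix.
#' @return Numeric vector of Fisher-z values, one per brain voxel.
#' @export
cluster_to_brain <- function(run, labels, cluster, brain) {
  stopifnot(inherits(run, "voxel_run"))
  if (length(labels) != nrow(run$data)) stop("labels/run size mismatch")
  members <- labels == cluster
  if (!any(members)) stop("empty cluster: ", cluster)
  brain <- as.matrix(brain)
  if (ncol(brain) != ncol(run$data)) stop("brain matrix time points mismatch")
  resid <- regress_nuisance(run)
  cl_mean <- colMeans(resid[members, , drop = FALSE])
  # regress the same nuisance out of the brain voxels for a like-for-like map
  X <- cbind(1, run$nuisance)
  brain_resid <- t(qr.resid(qr(X), t(brain)))
  z <- fisher_z(drop(stats::cor(cl_mean, t(brain_resid))))
  unname(z)
}

#' Fixed-effects (Stouffer) combination of z maps
#'
#' Combines N per-run z maps voxelwise as sum(z_i) / sqrt(N): evidence pools
#' across runs with fixed effects, so N identical maps scale by sqrt(N).
#'
#' @param maps List of numeric z vectors on one grid.
#' @param method `"stouffer"` (default) or `"mean"` (plain averaging; same
#'   ranking, different scale).
#' @return A `brain_z_map`: list with `z`, `n_runs_combined`, `method`.
#' @export
fixed_effects_combine <- function(maps, method = c("stouffer", "mean")) {
  method <- match.arg(method)
  stopifnot(length(maps) >= 1L)
  len <- unique(vapply(maps, length, integer(1)))
  if (length(len) != 1L) stop("maps must share one grid")
  zsum <- Reduce(`+`, maps)
  z <- if (method == "stouffer") zsum / sqrt(length(maps)) else zsum / length(maps)
  structure(list(z = z, n_runs_combined = length(maps), method = method),
            class = "brain_z_map")
}

#' Threshold a group z map
#'
#' Retains voxels with z strictly above the threshold; others are set to the
#' background value. Survival counts are recorded for the summary CSV.
#'
#' @param map A `brain_z_map` (or plain numeric z vector).
#' @param z_threshold Threshold (default 2.3); strictly greater survives.
#' @param background Value assigned to sub-threshold voxels (default 0).
#' @return List: `z` (thresholded values), `mask` (logical), `n_surviving`,
#'   `z_threshold`.
#' @export
threshold_map <- function(map, z_threshold = 2.3, background = 0) {
  z <- if (inherits(map, "brain_z_map")) map$z else as.numeric(map)
  keep <- z > z_threshold
  out <- ifelse(keep, z, background)
  list(z = out, mask = keep, n_surviving = sum(keep), z_threshold = z_threshold)
}
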