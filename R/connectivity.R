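# Group-level voxelwise connectivity: per-run partial correlation matrices,
# Fisher z-transformation, two-stage (runs-then-subjects) averaging, and the
# Euclidean profile distance fed to clustering.

#' Voxelwise partial-correlation matrix for one run
#'
#' Pearson correlation between every pair of voxels after regressing the run's
#' nuisance series (plus an intercept) out of each voxel — i.e. the partial
#' correlation of each voxel pair controlling for the nuisance set. The run is
#' expected to be bandpass-filtered already.
#'
#' @param run A [voxel_run], typically the output of [bandpass()].
#' @return Symmetric voxels x voxels correlation matrix with unit diagonal.
#' @export
run_connectivity <- function(run) {
  resid <- regress_nuisance(run)
  sds <- apply(resid, 1L, stats::sd)
  in_sds <- apply(run$data, 1L, stats::sd)
  degenerate <- sds == 0 | sds < 1e-8 * pmax(in_sds, .Machine$double.eps)
  if (any(degenerate)) {
    stop(sprintf("zero-variance residual for voxel %d in run %s",
                 which(degenerate)[1L], run$run_id))
  }
  r <- stats::cor(t(resid))
  dimnames(r) <- NULL
  r
}

#' Fisher r-to-z transformation
#'
#' `atanh(r)` with `|r|` clipped to `1 - 1e-7` first, so perfect correlations
#' map to a large finite z instead of infinity.
#'
#' @param r Correlations in \[-1, 1\] (vector or matrix).
#' @return z-scores of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1: not a correlation")
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Two-stage group average of Fisher-z matrices
#'
#' Averages z-matrices across runs within each subject, then across subjects,
#' so subjects with unequal run counts carry equal weight. The diagonal of the
#' result is forced to 0 by convention (the self-correlation z is meaningless
#' after clipping).
#'
#' @param per_run_z Named list (one element per subject) of lists of z-matrices.
#' @return A `group_z` object: list with `z` (symmetric matrix, zero diagonal),
#'   `n_subjects`, `n_runs_per_subject`.
#' @export
average_group <- function(per_run_z) {
  stopifnot(is.list(per_run_z), length(per_run_z) >= 1L)
  dims <- unique(lapply(per_run_z, function(sub) unique(lapply(sub, dim))))
  dims <- unique(do.call(c, dims))
  if (length(dims) != 1L) stop("all z-matrices must share one shape")
  subject_means <- lapply(per_run_z, function(sub) {
    if (length(sub) < 1L) stop("every subject needs at least one run")
    Reduce(`+`, sub) / length(sub)
  })
  z <- Reduce(`+`, subject_means) / length(subject_means)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  structure(
    list(z = z,
         n_subjects = length(per_run_z),
         n_runs_per_subject = vapply(per_run_z, length, integer(1))),
    class = "group_z"
  )
}

#' @export
print.group_z <- function(x, ...) {
  cat(sprintf("<group_z: %d voxels, %d subjects, runs per subject: %s>\n",
              nrow(x$z), x$n_subjects, paste(x$n_runs_per_subject, collapse = "/")))
  invisible(x)
}

#' Euclidean distance between connectivity profiles
#'
#' Pairwise Euclidean distance between the rows of the group z-matrix: voxels
#' with similar connectivity profiles end up close. Diagonal self-entries
#' participate with their 0-convention value.
#'
#' @param gz A `group_z` object from [average_group()], or any numeric matrix
#'   whose rows are profiles.
#' @return Symmetric nonnegative distance matrix with zero diagonal.
#' @export
profile_distance <- function(gz) {
  m <- if (inherits(gz, "group_z")) gz$z else as.matrix(gz)
  if (!all(is.finite(m))) stop("non-finite entries in the profile matrix")
  as.matrix(stats::dist(m, method = "euclidean"))
}
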