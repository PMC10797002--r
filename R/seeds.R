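# Seed-sphere geometry against a template grid (dimensions + 4x4 affine).

#' Define a template grid
#'
#' @param dim Integer vector of 3 grid dimensions.
#' @param affine 4x4 voxel-index-to-world-mm affine (0-based indices);
#'   default: identity scaled by `spacing`.
#' @param spacing Isotropic voxel size in mm used when `affine` is NULL.
#' @return A `template_grid` list.
#' @export
template_grid <- function(dim, affine = NULL, spacing = 1) {
  stopifnot(length(dim) == 3L, all(dim >= 1))
  if (is.null(affine)) {
    affine <- diag(c(spacing, spacing, spacing, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  structure(list(dim = as.integer(dim), affine = affine), class = "template_grid")
}

#' Resolve a seed sphere to grid voxel indices
#'
#' Returns the 0-based flat indices (column-major scan, x fastest — R array
#' order, recorded in run manifests) of all voxels
#' whose center lies within `radius` mm (inclusive) of the seed center in
#' world coordinates.
#'
#' @param seed List with `name`, `center` (length-3 world mm), `radius`
#'   (mm, default 2 — the conventional seed-sphere size).
#' @param grid A [template_grid()].
#' @return Sorted integer vector of 0-based voxel indices.
#' @export
resolve_seed_voxels <- function(seed, grid) {
  stopifnot(inherits(grid, "template_grid"))
  center <- as.numeric(seed$center)
  radius <- if (is.null(seed$radius)) 2 else seed$radius
  if (length(center) != 3L || radius <= 0) stop("seed needs a 3-d center and radius > 0")
  # world coordinates of all voxel centers would be large; bound the search
  # box by inverting the affine around the seed center
  inv <- solve(grid$affine)
  cvox <- drop(inv %*% c(center, 1))[1:3]
  # conservative half-width in voxels from the affine's column norms
  col_norm <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  halfw <- ceiling(radius / min(col_norm)) + 1L
  rng <- lapply(1:3, function(a) {
    lo <- max(0L, floor(cvox[a] - halfw)); hi <- min(grid$dim[a] - 1L, ceiling(cvox[a] + halfw))
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0L)) stop("seed '", seed$name, "' resolves to no voxels in the grid")
  idx <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  world <- cbind(idx, 1) %*% t(grid$affine)
  d2 <- rowSums(sweep(world[, 1:3, drop = FALSE], 2L, center)^2)
  keep <- d2 <= radius^2 + 1e-9
  if (!any(keep)) stop("seed '", seed$name, "' resolves to no voxels in the grid")
  flat <- idx[keep, 1] + grid$dim[1] * (idx[keep, 2] + grid$dim[2] * idx[keep, 3])
  sort(as.integer(flat))
}
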