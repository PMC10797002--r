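# Unweighted average-linkage (UPGMA) agglomerative clustering of the profile
# distance matrix, tree cutting at K = 2..10, and label reordering along a
# spatial axis.

#' UPGMA hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering where the distance between two clusters is the
#' unweighted mean of all cross-pair distances. Candidate merges with tied
#' distances are resolved by the lowest pair index (clusters indexed by their
#' creation order, leaves first), so dendrograms are reproducible.
#'
#' @param d Symmetric nonnegative distance matrix (or `dist` object).
#' @return A `linkage_tree`: list with `merge` (m x 2, negative = leaf,
#'   positive = earlier merge, as in [stats::hclust()]), `height`, `size`
#'   (cluster sizes after each merge), and `n_leaves`.
#' @export
linkage_upgma <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-10)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be nonnegative")
  n <- nrow(d)
  if (n < 2L) stop("need at least two items to cluster")

  # active cluster bookkeeping; ids: 1..n leaves, n+j for merge j
  work <- d
  diag(work) <- Inf
  size <- rep(1L, n)
  id <- -(seq_len(n))              # hclust coding: negative leaf index
  order_rank <- seq_len(n)         # creation order for tie-breaking
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- work[idx, idx, drop = FALSE]
    best <- min(sub)
    # ties: lowest (creation-order) pair index, row-major
    cand <- which(sub <= best + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ra <- order_rank[idx[cand[, 1]]]; rb <- order_rank[idx[cand[, 2]]]
    ord <- order(pmin(ra, rb), pmax(ra, rb))
    pick <- cand[ord[1L], ]
    i <- idx[pick[1L]]; j <- idx[pick[2L]]

    merge[step, ] <- sort(c(id[i], id[j]))  # leaves (<0) before merges, hclust-style
    height[step] <- work[i, j]
    msize[step] <- size[i] + size[j]

    # Lance-Williams UPGMA update into slot i; retire slot j
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      newd <- (size[i] * work[i, others] + size[j] * work[j, others]) / (size[i] + size[j])
      work[i, others] <- newd
      work[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    order_rank[i] <- n + step
    active[j] <- FALSE
  }

  structure(list(merge = merge, height = height, size = msize, n_leaves = n),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree: %d leaves, %d merges, heights %.4g .. %.4g>\n",
              x$n_leaves, nrow(x$merge), min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a linkage tree to an hclust object
#'
#' @param tree A `linkage_tree` from [linkage_upgma()].
#' @return A [stats::hclust] object (method "average").
#' @export
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  # leaf order for plotting: left-to-right traversal of the merge tree
  leaf_order <- function(node) {
    if (node < 0) return(-node)
    c(leaf_order(tree$merge[node, 1]), leaf_order(tree$merge[node, 2]))
  }
  structure(
    list(merge = tree$merge, height = tree$height,
         order = leaf_order(nrow(tree$merge)),
         labels = NULL, method = "average",
         call = match.call(), dist.method = "euclidean"),
    class = "hclust"
  )
}

#' Export a linkage tree as a Newick string
#'
#' @param tree A `linkage_tree`.
#' @param labels Optional leaf labels (default `v1..vn`).
#' @return Newick string (also usable with `ape::read.tree(text = )`).
#' @export
tree_to_newick <- function(tree, labels = NULL) {
  hc <- as_hclust(tree)
  hc$labels <- if (is.null(labels)) paste0("v", seq_len(tree$n_leaves)) else labels
  ape::write.tree(ape::as.phylo(hc))
}

#' Cut a linkage tree into K clusters
#'
#' Removes the K-1 highest merges and labels the resulting components 1..K in
#' order of their lowest member voxel index, so labels are deterministic.
#'
#' @param tree A `linkage_tree`.
#' @param k Number of clusters, between 1 and the leaf count.
#' @return A `cluster_solution`: list with `k` and integer `labels`.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- tree$n_leaves
  assert_count(k, "k")
  if (k > n) stop(sprintf("k = %d exceeds the number of voxels (%d)", k, n))
  labels <- rep(1L, n)
  if (k > 1L) {
    # union-find over the first n-k merges (the k-1 highest are dropped;
    # UPGMA heights are monotone so merge order == height order)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    roots <- integer(n - 1L)  # root leaf of each merge's component
    for (s in seq_len(n - k)) {
      a <- tree$merge[s, 1]; b <- tree$merge[s, 2]
      la <- if (a < 0) -a else roots[a]
      lb <- if (b < 0) -b else roots[b]
      ra <- find(la); rb <- find(lb)
      parent[max(ra, rb)] <- min(ra, rb)
      roots[s] <- min(ra, rb)
    }
    comp <- vapply(seq_len(n), find, integer(1))
    labels <- as.integer(factor(comp, levels = sort(unique(comp))))
  }
  structure(list(k = as.integer(k), labels = labels), class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution: k = %d, sizes %s>\n", x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Reorder cluster ids along a spatial axis
#'
#' Relabels clusters so id 1 has the lowest mean coordinate on the given axis
#' (e.g. anterior to posterior), without changing the partition. Ties keep the
#' lower original id first.
#'
#' @param sol A `cluster_solution`.
#' @param coords Numeric vector (or matrix with `axis` selecting a column) of
#'   per-voxel positions.
#' @param axis Column of `coords` to use when it is a matrix (default 1).
#' @return Relabelled `cluster_solution` with a `relabeling` map attached.
#' @export
relabel_along_axis <- function(sol, coords, axis = 1L) {
  stopifnot(inherits(sol, "cluster_solution"))
  if (is.matrix(coords)) coords <- coords[, axis]
  if (length(coords) != length(sol$labels) || anyNA(coords)) {
    stop("coords must provide one finite position per voxel")
  }
  means <- vapply(seq_len(sol$k), function(c) mean(coords[sol$labels == c]), numeric(1))
  new_of_old <- integer(sol$k)
  new_of_old[order(means, seq_len(sol$k))] <- seq_len(sol$k)
  sol$labels <- new_of_old[sol$labels]
  sol$relabeling <- new_of_old
  sol
}
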