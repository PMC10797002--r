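# Cluster-count selection via three criteria: seed-fingerprint permutation
# testing (cosine similarity of normalized fingerprints under a per-subject
# label-exchange null), mean silhouette, and the within-cluster sum-of-squares
# elbow; plus a consensus rule over the three votes.

#' Seed fingerprints of each cluster, per subject
#'
#' For every run, the mean time course of each cluster (average over its
#' voxels) is correlated with the mean time course of each external seed; the
#' correlations are Fisher z-transformed and averaged across the subject's
#' runs. One fingerprint per (subject, cluster).
#'
#' @param sol A `cluster_solution` labelling the mask voxels.
#' @param runs_by_subject Named list (subject -> list of [voxel_run]), already
#'   bandpassed; voxels are nuisance-regressed internally before correlation.
#' @param seeds_by_subject Named list (subject -> list of seed matrices,
#'   time points x n_seeds), aligned with `runs_by_subject`.
#' @return A `fingerprint_set`: 3-d array subjects x clusters x seeds with a
#'   `class` attribute, plus dimnames.
#' @export
compute_fingerprints <- function(sol, runs_by_subject, seeds_by_subject) {
  stopifnot(inherits(sol, "cluster_solution"))
  subjects <- names(runs_by_subject)
  if (is.null(subjects) || !identical(sort(subjects), sort(names(seeds_by_subject)))) {
    stop("runs_by_subject and seeds_by_subject must be named lists over the same subjects")
  }
  counts <- tabulate(sol$labels, sol$k)
  if (any(counts == 0L)) stop("empty cluster in solution: ", which(counts == 0L)[1L])
  n_seeds <- ncol(seeds_by_subject[[1L]][[1L]])
  fp <- array(NA_real_, dim = c(length(subjects), sol$k, n_seeds),
              dimnames = list(subjects, paste0("c", seq_len(sol$k)), NULL))
  for (s in subjects) {
    runs <- runs_by_subject[[s]]
    seeds <- seeds_by_subject[[s]]
    if (length(runs) != length(seeds)) {
      stop("subject ", s, ": run/seed list length mismatch")
    }
    zsum <- matrix(0, sol$k, n_seeds)
    for (r in seq_along(runs)) {
      run <- runs[[r]]
      if (ncol(run$data) != nrow(seeds[[r]])) {
        stop("subject ", s, " run ", r, ": seed time series length mismatch")
      }
      resid <- regress_nuisance(run)
      cl_mean <- t(vapply(seq_len(sol$k),
                          function(c) colMeans(resid[sol$labels == c, , drop = FALSE]),
                          numeric(ncol(run$data))))
      zsum <- zsum + fisher_z(stats::cor(t(cl_mean), seeds[[r]]))
    }
    fp[s, , ] <- zsum / length(runs)
  }
  structure(fp, class = "fingerprint_set")
}

# Extract the subjects x seeds matrix of one cluster from a fingerprint set.
fingerprint_cluster <- function(fps, cluster) {
  stopifnot(inherits(fps, "fingerprint_set"))
  m <- unclass(fps)[, cluster, , drop = FALSE]
  matrix(m, nrow = dim(fps)[1L], dimnames = list(dimnames(fps)[[1L]], NULL))
}

#' Observed cosine similarity between two clusters' fingerprints
#'
#' Averages each cluster's per-subject fingerprints across subjects, min-max
#' normalizes each group-mean fingerprint to \[0, 1\] (a constant fingerprint
#' maps to all 0.5), and returns the cosine of the two normalized vectors.
#'
#' @param fps_a,fps_b Subjects x seeds matrices (same subjects, same seeds).
#' @return Cosine similarity in \[-1, 1\].
#' @export
normalize_and_compare <- function(fps_a, fps_b) {
  fps_a <- as.matrix(fps_a); fps_b <- as.matrix(fps_b)
  if (!all(dim(fps_a) == dim(fps_b))) stop("fingerprint matrices must share a shape")
  cosine_similarity(minmax_normalize(colMeans(fps_a)),
                    minmax_normalize(colMeans(fps_b)))
}

# All swap patterns (rows) for exhaustive enumeration: 2^n x n 0/1 matrix.
swap_patterns <- function(n_subjects) {
  m <- as.matrix(expand.grid(rep(list(0:1), n_subjects)))
  dimnames(m) <- NULL
  m
}

# Vectorized cosine similarities for a 0/1 swap-pattern matrix: row p swaps
# the a/b fingerprints of subjects with pattern 1 before group averaging.
permuted_cosines <- function(fps_a, fps_b, patterns) {
  n <- nrow(fps_a)
  base_a <- colMeans(fps_a); base_b <- colMeans(fps_b)
  delta <- (fps_b - fps_a) / n
  Ma <- matrix(base_a, nrow(patterns), length(base_a), byrow = TRUE) + patterns %*% delta
  Mb <- matrix(base_b, nrow(patterns), length(base_b), byrow = TRUE) - patterns %*% delta
  vapply(seq_len(nrow(patterns)), function(p) {
    cosine_similarity(minmax_normalize(Ma[p, ]), minmax_normalize(Mb[p, ]))
  }, numeric(1))
}

#' Permutation test for distinct fingerprints of a cluster pair
#'
#' Null: the two clusters share one fingerprint, so swapping the pair's labels
#' within any subject leaves the distribution unchanged. Each iteration swaps
#' the a/b fingerprints independently per subject with probability 1/2,
#' recomputes group means, normalization and cosine. Low observed similarity
#' relative to the null (most permutation cosines larger) gives a small p.
#' When `2^n_subjects <= n_perm` the full permutation set is enumerated and
#' the p-value is exact; otherwise a Monte-Carlo p with add-one correction is
#' returned.
#'
#' @param fps_a,fps_b Subjects x seeds fingerprint matrices.
#' @param n_perm Number of permutations (default 100000).
#' @param rng_seed Seed for the Monte-Carlo branch.
#' @return List: `cosine` (observed), `p_value`, `n_permutations`, `exact`.
#' @export
permutation_test_pair <- function(fps_a, fps_b, n_perm = 100000L, rng_seed = 1L) {
  fps_a <- as.matrix(fps_a); fps_b <- as.matrix(fps_b)
  n <- nrow(fps_a)
  if (n < 2L) stop("permutation null undefined for fewer than 2 subjects")
  assert_count(n_perm, "n_perm")
  observed <- normalize_and_compare(fps_a, fps_b)
  exact <- n <= 30 && 2^n <= n_perm
  if (exact) {
    cos_perm <- permuted_cosines(fps_a, fps_b, swap_patterns(n))
    p <- sum(cos_perm <= observed + 1e-12) / length(cos_perm)
    n_used <- length(cos_perm)
  } else {
    patterns <- with_seed(rng_seed,
      matrix(stats::rbinom(n_perm * n, 1L, 0.5), n_perm, n))
    cos_perm <- permuted_cosines(fps_a, fps_b, patterns)
    p <- (1 + sum(cos_perm <= observed + 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(cosine = observed, p_value = p, n_permutations = n_used, exact = exact)
}

#' Fingerprint criterion over a range of cluster counts
#'
#' For each K, cuts the tree, computes fingerprints, and tests every pair of
#' clusters; the criterion selects the largest K for which all K(K-1)/2 pairs
#' are significantly different (p < alpha). Returns 1 if no K qualifies.
#'
#' @param tree A `linkage_tree`.
#' @param runs_by_subject,seeds_by_subject As in [compute_fingerprints()].
#' @param k_range Candidate cluster counts (default 2:10).
#' @param n_perm,alpha Permutation count and significance level.
#' @param rng_seed Seed for Monte-Carlo permutations.
#' @return List: `k` (chosen), `pairs` (data frame: k, cluster_a, cluster_b,
#'   cosine, p_value, significant), `all_significant` (named logical per K).
#' @export
fingerprint_criterion <- function(tree, runs_by_subject, seeds_by_subject,
                                  k_range = 2:10, n_perm = 100000L,
                                  alpha = 0.05, rng_seed = 1L) {
  rows <- list()
  all_sig <- logical(0)
  for (k in k_range) {
    sol <- cut_tree(tree, k)
    fps <- compute_fingerprints(sol, runs_by_subject, seeds_by_subject)
    sig_k <- TRUE
    for (a in seq_len(k - 1L)) {
      for (b in seq((a + 1L), k)) {
        res <- permutation_test_pair(fingerprint_cluster(fps, a),
                                     fingerprint_cluster(fps, b),
                                     n_perm = n_perm,
                                     rng_seed = derive_seed(rng_seed, k * 1000L + a * 31L + b))
        rows[[length(rows) + 1L]] <- data.frame(
          k = k, cluster_a = a, cluster_b = b,
          cosine = res$cosine, p_value = res$p_value,
          significant = res$p_value < alpha)
        sig_k <- sig_k && res$p_value < alpha
      }
    }
    all_sig[as.character(k)] <- sig_k
  }
  ks <- as.integer(names(all_sig))[all_sig]
  list(k = if (length(ks)) max(ks) else 1L,
       pairs = do.call(rbind, rows),
       all_significant = all_sig)
}

#' Mean silhouette of a cluster solution
#'
#' Standard silhouette coefficient per voxel computed from the precomputed
#' distance matrix (a(i): mean distance to own cluster, b(i): smallest mean
#' distance to another cluster; s(i) = (b - a) / max(a, b); singletons get 0),
#' averaged over voxels.
#'
#' @param d Distance matrix.
#' @param sol A `cluster_solution` with k >= 2.
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_mean <- function(d, sol) {
  stopifnot(inherits(sol, "cluster_solution"))
  if (sol$k < 2L) stop("silhouette requires at least 2 clusters")
  d <- as.matrix(d)
  labels <- sol$labels
  if (length(labels) != nrow(d)) stop("labels/distance size mismatch")
  sizes <- tabulate(labels, sol$k)
  if (any(sizes == 0L)) stop("empty cluster")
  # mean distance from every voxel to every cluster (own cluster excludes self)
  sums <- vapply(seq_len(sol$k),
                 function(c) rowSums(d[, labels == c, drop = FALSE]), numeric(nrow(d)))
  s <- vapply(seq_len(nrow(d)), function(i) {
    c_own <- labels[i]
    if (sizes[c_own] == 1L) return(0)
    a <- sums[i, c_own] / (sizes[c_own] - 1L)
    b <- min(sums[i, -c_own] / sizes[-c_own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Within-cluster sum of squares for nested solutions
#'
#' WSS(K) = sum over clusters of the squared Euclidean deviations of the
#' member voxels' connectivity profiles from their cluster centroid, computed
#' in the same z-profile space used for the distances.
#'
#' @param gz A `group_z` object (or profile matrix).
#' @param sols List of `cluster_solution`s (typically cuts of one tree).
#' @return Named numeric vector of WSS per K.
#' @export
wss_curve <- function(gz, sols) {
  m <- if (inherits(gz, "group_z")) gz$z else as.matrix(gz)
  vapply(sols, function(sol) {
    if (length(sol$labels) != nrow(m)) stop("labels/profile-matrix size mismatch")
    total <- 0
    for (c in seq_len(sol$k)) {
      rows <- m[sol$labels == c, , drop = FALSE]
      centroid <- colMeans(rows)
      total <- total + sum(sweep(rows, 2L, centroid)^2)
    }
    total
  }, numeric(1)) -> wss
  names(wss) <- vapply(sols, function(s) as.character(s$k), character(1))
  wss
}

#' Elbow of a within-cluster sum-of-squares curve
#'
#' Returns the K maximizing the discrete second difference
#' WSS(K-1) - 2 WSS(K) + WSS(K+1), i.e. where the curve bends from steep to
#' shallow decline. A flat/linear curve has no elbow: the smallest interior K
#' is returned with a warning.
#'
#' @param wss Named numeric vector (names = K) over at least 4 values of K.
#' @return List: `k`, `second_differences` (named), `no_elbow` flag.
#' @export
elbow_point <- function(wss) {
  if (length(wss) < 4L) stop("elbow needs a curve over at least 4 values of K")
  ks <- as.integer(names(wss))
  if (anyNA(ks) || is.unsorted(ks)) stop("wss must be named by increasing K")
  inner <- 2:(length(wss) - 1L)
  d2 <- wss[inner - 1L] - 2 * wss[inner] + wss[inner + 1L]
  names(d2) <- ks[inner]
  spread <- diff(range(d2))
  scale <- max(abs(wss))
  no_elbow <- spread <= 1e-10 * max(scale, 1)
  if (no_elbow) {
    warning("no elbow: second differences are constant; returning smallest K")
    k <- ks[inner[1L]]
  } else {
    k <- ks[inner[which.max(d2)]]
  }
  list(k = k, second_differences = d2, no_elbow = no_elbow)
}

# Silhouette vote: K whose mean silhouette is an interior local peak (exceeds
# both neighbours); among several peaks the highest wins; if no interior peak
# exists, the global argmax is used.
silhouette_vote <- function(sil) {
  ks <- as.integer(names(sil))
  if (length(sil) < 3L) return(ks[which.max(sil)])
  inner <- 2:(length(sil) - 1L)
  peaks <- inner[sil[inner] > sil[inner - 1L] & sil[inner] > sil[inner + 1L]]
  if (length(peaks) == 0L) return(ks[which.max(sil)])
  ks[peaks[which.max(sil[peaks])]]
}

#' Consensus cluster count from the three validation criteria
#'
#' Majority vote among the fingerprint K, the elbow K, and the silhouette
#' local-peak K. With three distinct votes the fingerprint K wins, as the only
#' inferential criterion.
#'
#' @param fingerprint_k,elbow_k,silhouette_k The three votes.
#' @return List: `k`, `votes` (named), `rationale` string.
#' @export
consensus_k <- function(fingerprint_k, elbow_k, silhouette_k) {
  votes <- c(fingerprint = fingerprint_k, elbow = elbow_k, silhouette = silhouette_k)
  tab <- table(votes)
  if (max(tab) >= 2L) {
    k <- as.integer(names(tab)[which.max(tab)])
    why <- sprintf("majority vote (%d of 3)", max(tab))
  } else {
    k <- as.integer(fingerprint_k)
    why <- "no majority; fingerprint criterion takes precedence (only inferential criterion)"
  }
  list(k = k, votes = votes,
       rationale = sprintf("votes fingerprint=%d elbow=%d silhouette=%d; chose K=%d: %s",
                           votes[1L], votes[2L], votes[3L], k, why))
}
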