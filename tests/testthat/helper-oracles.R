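# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive results by brute force or closed form, on paths
# disjoint from the package implementation.

# Build a 2-voxel run whose single pairwise correlation is exactly `r`.
run_with_mean_correlation <- function(r, n_time = 60, run_id = "R1", seed = 1) {
  set.seed(seed)
  v1 <- rnorm(n_time); v2 <- rnorm(n_time)
  x <- as.numeric(scale(v1))
  z <- residuals(lm(v2 ~ v1))
  z <- as.numeric(scale(z))
  y <- r * x + sqrt(1 - r^2) * z
  voxel_run(rbind(x, y), tr_seconds = 2, run_id = run_id, fixation_fraction = 1)
}

# Closed-form partial correlation of x and y given columns of Z, via the
# precision matrix of the stacked sample covariance.
partial_cor_oracle <- function(x, y, Z) {
  S <- stats::cov(cbind(x, y, Z))
  P <- solve(S)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Brute-force UPGMA: cluster distances recomputed from the original matrix by
# averaging all cross pairs at every step; ties broken by creation order of
# the pair (leaves first), matching the documented contract.
upgma_brute <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))     # member sets
  created <- seq_len(n)               # creation order per active cluster
  heights <- numeric(0)
  partitions <- list()                # partition after each merge
  merges <- 0L
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- Inf; bi <- NA; bj <- NA; bkey <- c(Inf, Inf)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        cd <- mean(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(created[i], created[j]))  # creation-order pair index
        better <- cd < best - 1e-12 ||
          (abs(cd - best) <= 1e-12 &&
           (key[1] < bkey[1] || (key[1] == bkey[1] && key[2] < bkey[2])))
        if (better) { best <- cd; bi <- i; bj <- j; bkey <- key }
      }
    }
    merged <- c(clusters[[bi]], clusters[[bj]])
    clusters <- clusters[-c(bi, bj)]
    created <- created[-c(bi, bj)]
    clusters[[length(clusters) + 1L]] <- merged
    merges <- merges + 1L
    created[length(clusters)] <- n + merges
    heights <- c(heights, best)
    labels <- integer(n)
    for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
    partitions[[merges]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

# Exhaustive-enumeration p-value for the fingerprint pair test, written as a
# plain loop over all 2^n subject swap assignments (independent of the
# vectorized implementation).
perm_p_brute <- function(fps_a, fps_b) {
  n <- nrow(fps_a)
  norm01 <- function(v) if (diff(range(v)) == 0) rep(0.5, length(v)) else
    (v - min(v)) / diff(range(v))
  cosim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  obs <- cosim(norm01(colMeans(fps_a)), norm01(colMeans(fps_b)))
  count <- 0L; total <- 0L
  for (code in 0:(2^n - 1)) {
    swap <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    A <- fps_a; B <- fps_b
    A[swap, ] <- fps_b[swap, ]; B[swap, ] <- fps_a[swap, ]
    cs <- cosim(norm01(colMeans(A)), norm01(colMeans(B)))
    total <- total + 1L
    if (cs <= obs + 1e-12) count <- count + 1L
  }
  list(p = count / total, observed = obs)
}

# Small preprocessed synthetic cohort shared by several tests.
make_small_cohort <- function(rng_seed = 11, n_voxels = 48, k_true = 3,
                              n_subjects = 3, n_runs = 2, n_volumes = 200,
                              n_seeds = 9) {
  cf <- synthetic_config(n_voxels = n_voxels, k_true = k_true, n_seeds = n_seeds,
                         n_subjects = n_subjects, n_runs_per_subject = n_runs,
                         n_volumes = n_volumes, rng_seed = rng_seed)
  ds <- generate_rest_dataset(cf)
  prep <- preprocess_cohort(ds$runs_by_subject, ds$seeds_by_subject)
  list(config = cf, truth = ds$truth, prep = prep)
}
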