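test_that("fingerprints hit the r = 1 cap, vanish for independent seeds, and track mixing", {
  cohort <- make_small_cohort()
  prep <- cohort$prep
  sol <- cut_tree(build_parcellation(prep$runs_by_subject)$tree, cohort$config$k_true)

  # seed identical to the cluster-1 mean time course -> clipped atanh(1)
  sub <- names(prep$runs_by_subject)[1]
  run <- prep$runs_by_subject[[sub]][[1]]
  resid <- regress_nuisance(run)
  seeds_clone <- lapply(prep$seeds_by_subject[[sub]],
                        function(m) cbind(colMeans(resid[sol$labels == 1, , drop = FALSE])))
  one_sub_runs <- stats::setNames(list(list(run)), sub)
  one_sub_seeds <- stats::setNames(list(seeds_clone[1]), sub)
  fps <- compute_fingerprints(sol, one_sub_runs, one_sub_seeds)
  expect_equal(unclass(fps)[1, 1, 1], atanh(1 - 1e-7), tolerance = 1e-9)

  # independent noise seed -> z near 0
  set.seed(1)
  noise_seed <- stats::setNames(list(list(cbind(rnorm(ncol(run$data))))), sub)
  fps0 <- compute_fingerprints(sol, one_sub_runs, noise_seed)
  expect_lt(abs(unclass(fps0)[1, 1, 1]), 0.4)

  # planted mixing: cluster c has the largest z for the seeds it drives
  fps_all <- compute_fingerprints(sol, prep$runs_by_subject, prep$seeds_by_subject)
  mix <- cohort$truth$seed_mixing
  # map solution labels to true communities (ARI 1 at k_true)
  grp <- apply(unclass(fps_all), c(2, 3), mean)  # clusters x seeds
  for (s in seq_len(ncol(mix))) {
    driver <- which.max(mix[, s])
    true_of_label <- vapply(seq_len(sol$k), function(c)
      unique(cohort$truth$labels[sol$labels == c])[1], integer(1))
    expect_equal(true_of_label[which.max(grp[, s])], driver)
  }

  expect_error(compute_fingerprints(structure(list(k = 5L, labels = sol$labels),
                                              class = "cluster_solution"),
                                    prep$runs_by_subject, prep$seeds_by_subject),
               "empty cluster")
})

test_that("normalize_and_compare matches hand arithmetic", {
  a <- rbind(c(0.2, 0.4, 0.6)); b <- rbind(c(0.6, 0.4, 0.2))
  # normalized: (0,0.5,1) vs (1,0.5,0) -> cos = 0.25 / 1.25 = 0.2
  expect_equal(normalize_and_compare(a, b), 0.2, tolerance = 1e-12)
  expect_equal(normalize_and_compare(a, a), 1)
  e1 <- rbind(c(5, 1, 1, 1)); e2 <- rbind(c(1, 5, 1, 1))  # normalize to disjoint support
  expect_equal(normalize_and_compare(e1, e2), 0)
})

test_that("permutation test: identical pair gives p = 1; 2 subjects enumerate 4 patterns", {
  set.seed(2)
  fps <- matrix(rnorm(2 * 5), 2, 5)
  res <- permutation_test_pair(fps, fps, n_perm = 100)
  expect_equal(res$p_value, 1)
  expect_true(res$exact)
  expect_equal(res$n_permutations, 4L)  # 2^2 assignments
  expect_error(permutation_test_pair(fps[1, , drop = FALSE], fps[1, , drop = FALSE]),
               "fewer than 2 subjects")
})

test_that("exact p matches brute-force enumeration; Monte-Carlo agrees within 3 SE", {
  set.seed(31)
  for (case in 1:5) {
    n_sub <- sample(3:6, 1)
    pair <- generate_null_fingerprint_pair(n_seeds = 7, n_subjects = n_sub,
                                           noise_sd = 0.3, rng_seed = 100 + case)
    res <- permutation_test_pair(pair$fps_a, pair$fps_b, n_perm = 5000)
    oracle <- perm_p_brute(pair$fps_a, pair$fps_b)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
    expect_equal(res$cosine, oracle$observed, tolerance = 1e-12)
  }
  # force the Monte-Carlo branch with 10 subjects and n_perm < 2^10
  pair <- generate_null_fingerprint_pair(n_seeds = 9, n_subjects = 10,
                                         noise_sd = 0.3, rng_seed = 9)
  exact <- permutation_test_pair(pair$fps_a, pair$fps_b, n_perm = 2000)
  mc <- permutation_test_pair(pair$fps_a, pair$fps_b, n_perm = 1000, rng_seed = 4)
  expect_true(exact$exact); expect_false(mc$exact)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 1000)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 2 / 1000)
  # determinism of the Monte-Carlo branch
  mc2 <- permutation_test_pair(pair$fps_a, pair$fps_b, n_perm = 1000, rng_seed = 4)
  expect_identical(mc$p_value, mc2$p_value)
})

test_that("permutation test has power against well-separated fingerprints", {
  set.seed(5)
  rejections <- 0L
  n_rep <- 100
  for (i in 1:n_rep) {
    mean_a <- c(rep(1, 5), rep(0.1, 5)); mean_b <- c(rep(0.1, 5), rep(1, 5))
    fa <- matrix(mean_a, 8, 10, byrow = TRUE) + matrix(rnorm(80, sd = 0.25), 8, 10)
    fb <- matrix(mean_b, 8, 10, byrow = TRUE) + matrix(rnorm(80, sd = 0.25), 8, 10)
    res <- permutation_test_pair(fa, fb, n_perm = 512)
    if (res$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_rep, 0.9)
})

test_that("silhouette matches hand values and the cluster-package oracle", {
  d <- matrix(10, 4, 4); d[1, 2] <- d[2, 1] <- 1; d[3, 4] <- d[4, 3] <- 1; diag(d) <- 0
  sol <- structure(list(k = 2L, labels = c(1L, 1L, 2L, 2L)), class = "cluster_solution")
  expect_equal(silhouette_mean(d, sol), 0.9, tolerance = 1e-12)  # s = 1 - 1/10 each

  # two far-separated tight blobs -> mean ~ 1
  set.seed(14)
  pts <- rbind(matrix(rnorm(10, sd = 1e-3), 5, 2),
               matrix(rnorm(10, sd = 1e-3) + 100, 5, 2))
  dd <- as.matrix(dist(pts))
  solb <- structure(list(k = 2L, labels = rep(1:2, each = 5)), class = "cluster_solution")
  expect_gt(silhouette_mean(dd, solb), 0.99)

  # structureless data under random labels -> mean ~ 0
  set.seed(15)
  means <- replicate(10, {
    dr <- as.matrix(dist(matrix(rnorm(40 * 3), 40, 3)))
    lr <- sample(1:3, 40, replace = TRUE)
    silhouette_mean(dr, structure(list(k = 3L, labels = lr), class = "cluster_solution"))
  })
  expect_lt(abs(mean(means)), 0.1)

  # oracle: cluster::silhouette on random data
  skip_if_not_installed("cluster")
  set.seed(16)
  dr <- as.matrix(dist(matrix(rnorm(25 * 2), 25, 2)))
  lr <- sample(1:4, 25, replace = TRUE)
  while (length(unique(lr)) < 4) lr <- sample(1:4, 25, replace = TRUE)
  mine <- silhouette_mean(dr, structure(list(k = 4L, labels = lr), class = "cluster_solution"))
  oracle <- mean(cluster::silhouette(lr, dmatrix = dr)[, "sil_width"])
  expect_equal(mine, oracle, tolerance = 1e-10)

  expect_error(silhouette_mean(d, structure(list(k = 1L, labels = rep(1L, 4)),
                                            class = "cluster_solution")),
               "at least 2")
})

test_that("WSS limits, brute force, and monotonicity along nested cuts", {
  set.seed(17)
  m <- matrix(rnorm(12 * 5), 12, 5)
  sol1 <- structure(list(k = 1L, labels = rep(1L, 12)), class = "cluster_solution")
  soln <- structure(list(k = 12L, labels = 1:12), class = "cluster_solution")
  w <- wss_curve(m, list(sol1, soln))
  expect_equal(unname(w[2]), 0)
  expect_equal(unname(w[1]), sum(sweep(m, 2, colMeans(m))^2), tolerance = 1e-10)

  # two-pairs toy in profile space
  prof <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  sol2 <- structure(list(k = 2L, labels = c(1L, 1L, 2L, 2L)), class = "cluster_solution")
  brute <- sum((prof[1:2, ] - rep(1, 2) %o% colMeans(prof[1:2, ]))^2) +
    sum((prof[3:4, ] - rep(1, 2) %o% colMeans(prof[3:4, ]))^2)
  expect_equal(unname(wss_curve(prof, list(sol2))), brute, tolerance = 1e-12)

  tree <- linkage_upgma(as.matrix(dist(m)))
  sols <- lapply(2:10, function(k) cut_tree(tree, k))
  wss <- wss_curve(m, sols)
  expect_true(all(diff(wss) <= 1e-10))
})

test_that("elbow finds a constructed kink and flags linear curves", {
  k <- 2:10
  wss <- ifelse(k <= 4, 100 - 30 * (k - 2), 40 - 2 * (k - 4))  # kink at K = 4
  names(wss) <- k
  res <- elbow_point(wss)
  expect_equal(res$k, 4L)

  lin <- stats::setNames(100 - 5 * (k - 2), k)
  expect_warning(res2 <- elbow_point(lin), "no elbow")
  expect_equal(res2$k, 3L)  # smallest interior K
  expect_true(res2$no_elbow)

  expect_error(elbow_point(stats::setNames(c(3, 2, 1), 2:4)), "at least 4")
})

test_that("consensus applies majority vote with fingerprint precedence", {
  expect_equal(consensus_k(4, 4, 2)$k, 4L)
  expect_equal(consensus_k(4, 5, 2)$k, 4L)
  expect_equal(consensus_k(3, 5, 5)$k, 5L)
  expect_match(consensus_k(4, 5, 2)$rationale, "fingerprint")
})

test_that("fingerprint criterion recovers k_true and degrades gracefully", {
  # note: with n subjects the exact permutation test has 2^n patterns whose
  # complements pair up, so the smallest attainable p is 2/2^n; alpha = 0.05
  # therefore needs >= 6 subjects to be reachable at all
  cohort <- make_small_cohort(rng_seed = 19, n_subjects = 6, n_seeds = 9)
  parc <- build_parcellation(cohort$prep$runs_by_subject)
  fc <- fingerprint_criterion(parc$tree, cohort$prep$runs_by_subject,
                              cohort$prep$seeds_by_subject,
                              k_range = 2:6, n_perm = 2000, rng_seed = 5)
  expect_equal(fc$k, cohort$config$k_true)
  expect_true(all(c("k", "cluster_a", "cluster_b", "cosine", "p_value") %in%
                    colnames(fc$pairs)))

  # K range restricted to 2..2 on distinct planted structure -> returns 2
  fc2 <- fingerprint_criterion(parc$tree, cohort$prep$runs_by_subject,
                               cohort$prep$seeds_by_subject,
                               k_range = 2:2, n_perm = 2000, rng_seed = 5)
  expect_equal(fc2$k, 2L)

  # all communities sharing one mixing row -> no distinguishable pairs
  expect_warning(
    cf <- synthetic_config(n_voxels = 30, k_true = 3, n_seeds = 6, n_subjects = 6,
                           n_runs_per_subject = 2, n_volumes = 150,
                           seed_mixing = matrix(0.5, 3, 6), rng_seed = 23),
    "duplicated rows")
  ds <- generate_rest_dataset(cf)
  prep <- preprocess_cohort(ds$runs_by_subject, ds$seeds_by_subject)
  parc2 <- build_parcellation(prep$runs_by_subject)
  fc3 <- fingerprint_criterion(parc2$tree, prep$runs_by_subject, prep$seeds_by_subject,
                               k_range = 2:4, n_perm = 1000, rng_seed = 5)
  expect_equal(fc3$k, 1L)
})
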