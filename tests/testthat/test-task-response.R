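test_that("design builder reproduces printed run lengths and validates timing", {
  expect_equal(facial_expression_design()$n_volumes, 185L)
  expect_equal(grasping_design()$n_volumes, 305L)
  expect_equal(resting_design()$n_volumes, 300L)

  # explicit-length designs record their block/length gap instead of failing
  taste <- taste_design()
  expect_equal(taste$n_volumes, 185L)
  expect_gt(taste$length_discrepancy, 0L)
  vest <- vestibular_design()
  expect_equal(vest$n_volumes, 145L)

  empty <- build_block_design(NULL, tr_seconds = 2, start_volumes = 7L)
  expect_equal(empty$n_volumes, 7L)
  expect_equal(nrow(empty$events), 0L)

  expect_error(build_block_design(data.frame(condition = "a", duration_s = 3),
                                  tr_seconds = 2), "divisible")
  expect_error(build_block_design(data.frame(condition = "a", duration_s = 30),
                                  tr_seconds = 2, n_volumes = 10L), "n_volumes")
})

test_that("HRF regressors: zero-duration condition, plateau, MION sign convention", {
  d <- build_block_design(data.frame(condition = c("on", "off"),
                                     duration_s = c(0, 60)),
                          tr_seconds = 2, start_volumes = 5L, n_volumes = 120L)
  X <- hrf_regressors(d, "BOLD")
  expect_equal(max(abs(X[, "on"])), 0)

  # single long block: plateau approaches the HRF integral
  long <- build_block_design(data.frame(condition = "block", duration_s = 200),
                             tr_seconds = 2, start_volumes = 5L, n_volumes = 150L)
  for (kind in c("BOLD", "MION")) {
    Xl <- hrf_regressors(long, kind)
    h <- rsparcel:::hrf_kernel(kind, dt = 2)
    plateau_target <- abs(sum(h) * 2)      # integral at TR sampling
    plateau <- unname(abs(Xl[90, "block"]))  # t = 178 s, deep inside the block
    expect_equal(plateau, plateau_target, tolerance = 0.01 * plateau_target)
  }

  Xm_raw <- hrf_regressors(long, "MION", convention_flip = FALSE)
  Xb <- hrf_regressors(long, "BOLD")
  expect_lt(min(Xm_raw[, "block"]), 0)  # raw MION response is negative
  expect_gt(max(Xb[, "block"]), 0)
  expect_equal(attr(Xm_raw, "raw_sign"), -1)
  expect_error(rsparcel:::hrf_kernel("banana", 2), "unknown hrf_kind")
})

test_that("GLM recovers exact betas, ignores pure nuisance, flags rank deficiency", {
  d <- facial_expression_design()
  X <- hrf_regressors(d, "MION", conditions = c("lipsmack", "scrambled"))
  set.seed(6)
  nuis <- matrix(rnorm(d$n_volumes * 3), ncol = 3)

  y <- 2.0 * X[, "lipsmack"] + 100
  fit <- fit_glm(y, X, nuisance = nuis)
  expect_equal(unname(fit$betas["lipsmack", 1]), 2.0, tolerance = 1e-10)
  expect_equal(unname(fit$betas["intercept", 1]), 100, tolerance = 1e-8)

  y2 <- drop(nuis %*% c(1, -2, 3)) + 50
  fit2 <- fit_glm(y2, X, nuisance = nuis)
  expect_lt(max(abs(fit2$betas[c("lipsmack", "scrambled"), 1])), 1e-8)

  expect_error(fit_glm(y, cbind(X, X[, 1, drop = FALSE]), nuisance = nuis),
               "collinear")
})

test_that("percent signal change follows the MarsBaR-style formula", {
  d <- facial_expression_design()
  X <- hrf_regressors(d, "MION", conditions = c("lipsmack", "scrambled"))
  Xu <- sweep(X, 2, attr(X, "peaks"), "/")  # unit-peak regressors
  attr(Xu, "peaks") <- c(lipsmack = 1, scrambled = 1)

  # hand-built: betas (3, 1), intercept 200, unit peak -> 100*(3-1)*1/200 = 1.0
  y <- 200 + 3 * Xu[, "lipsmack"] + 1 * Xu[, "scrambled"]
  fit <- fit_glm(y, Xu)
  expect_equal(percent_signal_change(fit, "lipsmack", "scrambled"), 1.0,
               tolerance = 1e-8)
  expect_equal(percent_signal_change(fit, "lipsmack", "lipsmack"), 0)

  yneg <- -y
  fitneg <- fit_glm(yneg, Xu)
  expect_error(percent_signal_change(fitneg, "lipsmack", "scrambled"), "baseline")
  expect_error(percent_signal_change(fit, "nope"), "unknown condition")
})

test_that("planted 0.5% effect is recovered within 0.1 over noisy runs", {
  design <- facial_expression_design()
  labels <- rep(1:2, each = 5)
  task <- generate_task_dataset(design, c(lipsmack = 0.5, scrambled = 0), labels,
                                hrf_kind = "MION", noise_sd = 2, n_runs = 10,
                                rng_seed = 12)
  X <- hrf_regressors(design, "MION", conditions = c("lipsmack", "scrambled"))
  psc <- vapply(task$runs, function(run) {
    fit <- fit_glm(colMeans(run$data), X, nuisance = run$nuisance)
    percent_signal_change(fit, "lipsmack", "scrambled")
  }, numeric(1))
  expect_lt(abs(mean(psc) - 0.5), 0.1)
})

test_that("responsive-voxel selection keeps planted visual voxels", {
  design <- facial_expression_design()
  n_vox <- 12
  visual <- rep(c(TRUE, FALSE), each = n_vox / 2)
  effects <- matrix(0, 2, 2, dimnames = list(NULL, c("lipsmack", "scrambled")))
  effects[1, ] <- 2  # community 1 strongly visual in both conditions
  labels <- ifelse(visual, 1L, 2L)
  task <- generate_task_dataset(design, effects, labels, hrf_kind = "MION",
                                noise_sd = 0.5, n_runs = 1, rng_seed = 13)
  X <- hrf_regressors(design, "MION", conditions = c("lipsmack", "scrambled"))
  fit <- fit_glm(task$runs[[1]]$data, X, nuisance = task$runs[[1]]$nuisance)
  sel <- select_responsive_voxels(fit, c("lipsmack", "scrambled"), p_threshold = 0.001)
  expect_false(sel$empty)
  expect_identical(sel$keep, visual)

  # no visual voxel anywhere -> empty ROI flagged with a warning
  null_task <- generate_task_dataset(design, c(lipsmack = 0, scrambled = 0),
                                     labels, noise_sd = 1, n_runs = 1, rng_seed = 14)
  fit0 <- fit_glm(null_task$runs[[1]]$data, X, nuisance = null_task$runs[[1]]$nuisance)
  sel0 <- suppressWarnings(select_responsive_voxels(fit0, c("lipsmack", "scrambled"),
                                                    p_threshold = 1e-6))
  expect_true(sel0$empty)
})

test_that("PSC t-tests and Benjamini-Hochberg behave as computed by hand", {
  # all-zero PSC: t = 0, one-tailed p = 0.5
  res <- psc_ttest_fdr(list(roi1 = c(0, 0, 0, 0), roi2 = c(1, 2, 0.5, 1.5)))
  expect_equal(res$t[1], 0)
  expect_equal(res$p_raw[1], 0.5)
  expect_true(all(res$p_fdr >= res$p_raw - 1e-15))

  # hand BH: (0.01, 0.02, 0.20) -> (0.03, 0.03, 0.20)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.20), method = "BH"),
               c(0.03, 0.03, 0.20))

  # equal raw p-values stay equal after BH (via identical ROIs)
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res2 <- psc_ttest_fdr(same)
  expect_equal(res2$p_fdr, rep(res2$p_raw[1], 3))

  expect_error(psc_ttest_fdr(list(a = 1)), ">= 2 runs")

  # monotonicity property on random p-vectors
  set.seed(30)
  for (i in 1:20) {
    p <- runif(6)
    adj <- stats::p.adjust(p, "BH")
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})
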