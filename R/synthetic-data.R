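# Synthetic multi-subject resting-state and task fMRI with planted ground
# truth. The generator emulates the statistical structure the analysis
# assumes: K latent communities with band-limited slow signals, external
# seeds coupled to the communities through a mixing matrix, additive nuisance
# (white matter, ventricle, head motion) series, and block-design task runs
# with known percent-signal-change effects.

#' Configuration of the synthetic resting-state world
#'
#' Defaults state the emulated acquisition: 8 subjects x 3 runs of 300
#' volumes at TR 2 s (a 10-minute run), 100 mask voxels carrying 4 planted
#' communities, 23 external seeds, community SNR 2 (latent-signal sd over
#' noise sd), and a moderate nuisance amplitude.
#'
#' @param n_voxels Mask voxels.
#' @param k_true Planted community count.
#' @param n_seeds External seed regions.
#' @param n_subjects,n_runs_per_subject Cohort layout.
#' @param n_volumes,tr_seconds Run length and sampling interval (seconds).
#' @param community_snr Latent-signal sd divided by voxel noise sd.
#' @param seed_mixing `k_true x n_seeds` nonnegative weights coupling each
#'   community's latent signal into each seed; rows must be distinct for
#'   distinct fingerprints. Default: each community drives its own block of
#'   seeds strongly (weight 1) and all others weakly (0.1).
#' @param nuisance_amplitude Scale of the nuisance leakage into voxels,
#'   relative to unit noise sd.
#' @param baseline Additive raw-signal offset (arbitrary units).
#' @param rng_seed Integer seed; everything downstream is deterministic in it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_voxels = 100L, k_true = 4L, n_seeds = 23L,
                             n_subjects = 8L, n_runs_per_subject = 3L,
                             n_volumes = 300L, tr_seconds = 2,
                             community_snr = 2, seed_mixing = NULL,
                             nuisance_amplitude = 0.5, baseline = 1000,
                             rng_seed = 1L) {
  assert_count(n_voxels, "n_voxels"); assert_count(k_true, "k_true")
  assert_count(n_seeds, "n_seeds"); assert_count(n_subjects, "n_subjects")
  assert_count(n_runs_per_subject, "n_runs_per_subject")
  assert_count(n_volumes, "n_volumes", min = 8L)
  if (k_true > n_voxels) stop("k_true must not exceed n_voxels")
  stopifnot(tr_seconds > 0, community_snr >= 0, nuisance_amplitude >= 0)
  if (is.null(seed_mixing)) {
    seed_mixing <- matrix(0.1, k_true, n_seeds)
    # block-diagonal-ish strong couplings so rows are distinct
    block <- split(seq_len(n_seeds), rep(seq_len(k_true), length.out = n_seeds))
    for (c in seq_len(k_true)) seed_mixing[c, block[[c]]] <- 1
  }
  seed_mixing <- as.matrix(seed_mixing)
  if (!all(dim(seed_mixing) == c(k_true, n_seeds))) {
    stop("seed_mixing must be k_true x n_seeds")
  }
  if (any(seed_mixing < 0)) stop("seed_mixing must be nonnegative")
  if (anyDuplicated(as.data.frame(seed_mixing))) {
    warning("seed_mixing has duplicated rows: those communities will share a fingerprint")
  }
  structure(
    list(n_voxels = as.integer(n_voxels), k_true = as.integer(k_true),
         n_seeds = as.integer(n_seeds), n_subjects = as.integer(n_subjects),
         n_runs_per_subject = as.integer(n_runs_per_subject),
         n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
         community_snr = community_snr, seed_mixing = seed_mixing,
         nuisance_amplitude = nuisance_amplitude, baseline = baseline,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_config"
  )
}

# Band-limited latent signals: white Gaussian noise bandpassed into the
# 0.0025-0.05 Hz band (so the pipeline's own filter is structure-preserving),
# then standardized to unit sd. Columns are independent processes.
band_limited_signals <- function(n_volumes, n_signals, tr_seconds,
                                 low_hz = 0.0025, high_hz = 0.05) {
  x <- matrix(stats::rnorm(n_volumes * n_signals), n_volumes, n_signals)
  x <- bandpass_matrix(x, tr_seconds, low_hz, high_hz, order = 4)
  scale(x, center = TRUE, scale = apply(x, 2L, stats::sd))
}

# Smooth nuisance processes: independent Gaussian AR(1), unit marginal sd.
ar1_signals <- function(n_volumes, n_signals, phi = 0.9) {
  x <- matrix(stats::rnorm(n_volumes * n_signals), n_volumes, n_signals)
  for (t in 2:n_volumes) x[t, ] <- phi * x[t - 1L, ] + sqrt(1 - phi^2) * x[t, ]
  x
}

#' Generate a synthetic resting-state dataset with planted communities
#'
#' Each community c has a band-limited latent signal L_c(t) per run; a voxel
#' of community c emits `snr * L_c + nuisance leakage + unit noise` on top of
#' the baseline; seed s emits `sum_c mixing[c, s] * L_c + noise`. Communities
#' are contiguous blocks in the 1-D voxel ordering (the stand-in for mask
#' geometry). Nuisance series are returned separately so regression can
#' remove them.
#'
#' @param config A [synthetic_config()].
#' @return List: `runs_by_subject` (subject -> list of [voxel_run]),
#'   `seeds_by_subject` (subject -> list of time x n_seeds matrices),
#'   `truth` (list: labels, seed_mixing, config).
#' @export
generate_rest_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  labels <- sort(rep_len(seq_len(cf$k_true), cf$n_voxels))  # contiguous blocks
  with_seed(cf$rng_seed, {
    runs_by_subject <- list()
    seeds_by_subject <- list()
    for (s in seq_len(cf$n_subjects)) {
      sid <- sprintf("S%02d", s)
      runs <- list(); seeds <- list()
      for (r in seq_len(cf$n_runs_per_subject)) {
        L <- band_limited_signals(cf$n_volumes, cf$k_true, cf$tr_seconds)
        nuis <- ar1_signals(cf$n_volumes, 8L)  # WM, CSF, 6 motion
        colnames(nuis) <- c("wm", "csf", paste0("motion", 1:6))
        leak <- matrix(stats::runif(cf$n_voxels * 2L, 0.2, 1), cf$n_voxels, 2L)
        noise <- matrix(stats::rnorm(cf$n_voxels * cf$n_volumes), cf$n_voxels, cf$n_volumes)
        signal <- cf$community_snr * t(L[, labels, drop = FALSE]) +
          cf$nuisance_amplitude * (leak %*% t(nuis[, 1:2])) +
          noise + cf$baseline
        seed_noise <- matrix(stats::rnorm(cf$n_volumes * cf$n_seeds), cf$n_volumes, cf$n_seeds)
        seed_ts <- L %*% cf$seed_mixing + 0.5 * seed_noise
        fix <- stats::runif(1, 0.85, 1)
        runs[[r]] <- voxel_run(signal, nuisance = nuis, tr_seconds = cf$tr_seconds,
                               subject_id = sid, run_id = sprintf("%s_R%02d", sid, r),
                               fixation_fraction = fix)
        seeds[[r]] <- seed_ts
      }
      runs_by_subject[[sid]] <- runs
      seeds_by_subject[[sid]] <- seeds
    }
    list(runs_by_subject = runs_by_subject,
         seeds_by_subject = seeds_by_subject,
         truth = list(labels = labels, seed_mixing = cf$seed_mixing, config = cf))
  })
}

#' Generate a pair of null fingerprint sets
#'
#' Two clusters' per-subject fingerprints drawn i.i.d. around one shared mean
#' vector — the null of the fingerprint permutation test. Used to calibrate
#' its type-I error.
#'
#' @param n_seeds Fingerprint length.
#' @param n_subjects Subjects (>= 2).
#' @param noise_sd Per-subject deviation sd around the shared mean.
#' @param rng_seed Seed.
#' @param mean_fp Optional shared mean vector (default: a fixed smooth
#'   profile in \[0.2, 1\]).
#' @return List of two subjects x seeds matrices `fps_a`, `fps_b`.
#' @export
generate_null_fingerprint_pair <- function(n_seeds = 23L, n_subjects = 8L,
                                           noise_sd = 0.2, rng_seed = 1L,
                                           mean_fp = NULL) {
  assert_count(n_seeds, "n_seeds")
  if (n_subjects < 2L) stop("permutation null undefined for fewer than 2 subjects")
  if (is.null(mean_fp)) {
    mean_fp <- 0.6 + 0.4 * sin(seq(0, 3 * pi, length.out = n_seeds))
  }
  stopifnot(length(mean_fp) == n_seeds, noise_sd >= 0)
  with_seed(rng_seed, {
    draw <- function() matrix(mean_fp, n_subjects, n_seeds, byrow = TRUE) +
      matrix(stats::rnorm(n_subjects * n_seeds, sd = noise_sd), n_subjects, n_seeds)
    list(fps_a = draw(), fps_b = draw())
  })
}

#' Generate task runs with planted percent-signal-change effects
#'
#' Voxel signal is `baseline * (1 + sum_cond effect%/100 * regressor)` plus
#' Gaussian noise, where the regressors are the convention-flipped convolved
#' condition regressors scaled to unit peak — so the GLM/PSC pipeline should
#' recover the planted effect sizes directly.
#'
#' @param design A `block_design`.
#' @param planted_effects Named numeric vector: condition -> effect size in
#'   percent signal change, per community (recycled across communities when a
#'   single vector; or a matrix communities x conditions).
#' @param labels Per-voxel community labels.
#' @param hrf_kind `"MION"` or `"BOLD"`.
#' @param noise_sd Noise sd in raw signal units.
#' @param baseline Baseline signal level.
#' @param n_runs Number of runs to generate.
#' @param rng_seed Seed.
#' @return List: `runs` (list of [voxel_run] with 6-column motion nuisance),
#'   `regressors` (unit-peak matrix used for generation), `truth`
#'   (planted_effects, labels).
#' @export
generate_task_dataset <- function(design, planted_effects, labels,
                                  hrf_kind = c("MION", "BOLD"), noise_sd = 1,
                                  baseline = 1000, n_runs = 1L, rng_seed = 1L) {
  hrf_kind <- match.arg(hrf_kind)
  assert_count(n_runs, "n_runs")
  stopifnot(noise_sd >= 0, baseline > 0)
  conds <- if (is.matrix(planted_effects)) colnames(planted_effects) else names(planted_effects)
  if (is.null(conds) || !all(conds %in% design$conditions)) {
    stop("planted_effects must be named by conditions present in the design")
  }
  X <- hrf_regressors(design, hrf_kind, conditions = conds)
  Xu <- sweep(X, 2L, attr(X, "peaks"), "/")  # unit peak
  n_vox <- length(labels)
  with_seed(rng_seed, {
    runs <- lapply(seq_len(n_runs), function(r) {
      eff <- if (is.matrix(planted_effects)) {
        planted_effects[labels, , drop = FALSE]  # communities x conditions
      } else {
        matrix(planted_effects, n_vox, length(conds), byrow = TRUE)
      }
      clean <- baseline * (1 + (eff / 100) %*% t(Xu))
      nuis <- ar1_signals(design$n_volumes, 6L)
      colnames(nuis) <- paste0("motion", 1:6)
      data <- clean + matrix(stats::rnorm(n_vox * design$n_volumes, sd = noise_sd),
                             n_vox, design$n_volumes)
      voxel_run(data, nuisance = nuis, tr_seconds = design$tr_seconds,
                subject_id = "task", run_id = sprintf("task_R%02d", r),
                fixation_fraction = 1)
    })
    list(runs = runs, regressors = Xu,
         truth = list(planted_effects = planted_effects, labels = labels))
  })
}
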