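# End-to-end pipeline: QC -> conditioning -> group connectivity -> UPGMA ->
# K = 2..10 solutions -> three-criterion validation -> consensus K.

#' Run-level QC and signal conditioning for a cohort
#'
#' Applies the fixation filter and the mean-correlation outlier filter across
#' the pooled cohort, then bandpass-filters every retained run (voxels and
#' nuisance columns alike). Seed time series, when given, are subset to the
#' retained runs and bandpassed with the same band.
#'
#' @param runs_by_subject Named list: subject -> list of [voxel_run].
#' @param seeds_by_subject Optional named list aligned with `runs_by_subject`.
#' @param fixation_threshold Retention threshold (default 0.85).
#' @param low_hz,high_hz,order Bandpass parameters.
#' @param apply_correlation_filter Apply the median-outlier rule (default
#'   TRUE; needs >= 3 pooled runs).
#' @return List: `runs_by_subject`, `seeds_by_subject`, `qc_log` (data frame
#'   combining both filters' records).
#' @export
preprocess_cohort <- function(runs_by_subject, seeds_by_subject = NULL,
                              fixation_threshold = 0.85,
                              low_hz = 0.0025, high_hz = 0.05, order = 4,
                              apply_correlation_filter = TRUE) {
  subjects <- names(runs_by_subject)
  flat <- unlist(runs_by_subject, recursive = FALSE, use.names = FALSE)
  key <- unlist(lapply(subjects, function(s) {
    vapply(seq_along(runs_by_subject[[s]]), function(r) paste0(s, "::", r), character(1))
  }))
  fix <- filter_by_fixation(flat, threshold = fixation_threshold)
  keep1 <- fix$log$retained
  qc_log <- cbind(fix$log, filter = "fixation")
  keep2 <- keep1
  if (apply_correlation_filter && sum(keep1) >= 3L) {
    mc <- filter_by_mean_correlation(flat[keep1])
    keep2[keep1] <- mc$log$retained
    qc_log <- rbind(qc_log[, c("run_id", "subject_id", "retained", "reason", "filter")],
                    cbind(mc$log[, c("run_id", "subject_id", "retained", "reason")],
                          filter = "mean_correlation"))
  } else {
    qc_log <- qc_log[, c("run_id", "subject_id", "retained", "reason", "filter")]
  }
  out_runs <- list(); out_seeds <- if (is.null(seeds_by_subject)) NULL else list()
  for (s in subjects) {
    sel <- which(keep2[match(paste0(s, "::", seq_along(runs_by_subject[[s]])), key)])
    if (length(sel) == 0L) next
    out_runs[[s]] <- lapply(runs_by_subject[[s]][sel], bandpass,
                            low_hz = low_hz, high_hz = high_hz, order = order)
    if (!is.null(seeds_by_subject)) {
      out_seeds[[s]] <- lapply(seeds_by_subject[[s]][sel], function(m) {
        run_tr <- runs_by_subject[[s]][[1L]]$tr_seconds
        bandpass_matrix(as.matrix(m), run_tr, low_hz, high_hz, order)
      })
    }
  }
  if (length(out_runs) == 0L) stop("no runs survive quality control")
  list(runs_by_subject = out_runs, seeds_by_subject = out_seeds, qc_log = qc_log)
}

#' Group connectivity, distance matrix and UPGMA tree for a cohort
#'
#' Per run: voxelwise partial correlation (nuisance-controlled) and Fisher z;
#' then two-stage averaging (runs within subject, subjects within group),
#' Euclidean profile distance, and average-linkage clustering.
#'
#' @param runs_by_subject Preprocessed cohort (see [preprocess_cohort()]).
#' @return List: `group_z`, `distance`, `tree`.
#' @export
build_parcellation <- function(runs_by_subject) {
  per_run_z <- lapply(runs_by_subject, function(runs) {
    lapply(runs, function(run) fisher_z(run_connectivity(run)))
  })
  gz <- average_group(per_run_z)
  d <- profile_distance(gz)
  tree <- linkage_upgma(d)
  list(group_z = gz, distance = d, tree = tree)
}

#' Three-criterion validation of a parcellation
#'
#' Computes, over `k_range`: the fingerprint permutation criterion (largest K
#' with all pairwise cluster fingerprints distinct), the mean silhouette per
#' K (vote: best interior local peak), and the WSS elbow; then the consensus
#' K by majority vote with fingerprint precedence.
#'
#' @param parcellation Output of [build_parcellation()].
#' @param runs_by_subject,seeds_by_subject Preprocessed cohort and seeds.
#' @param k_range Candidate K (default 2:10).
#' @param n_perm Permutations per pair test (default 100000; exact
#'   enumeration is substituted when 2^subjects <= n_perm).
#' @param alpha Pairwise significance level (default 0.05).
#' @param rng_seed Seed for Monte-Carlo permutations.
#' @return A `validation_report`: list with `solutions`, `fingerprint`,
#'   `silhouette` (named per K), `wss`, `elbow`, `chosen_k`, `votes`,
#'   `rationale`.
#' @export
validate_parcellation <- function(parcellation, runs_by_subject, seeds_by_subject,
                                  k_range = 2:10, n_perm = 100000L,
                                  alpha = 0.05, rng_seed = 1L) {
  tree <- parcellation$tree
  sols <- lapply(k_range, function(k) cut_tree(tree, k))
  names(sols) <- k_range
  fp <- fingerprint_criterion(tree, runs_by_subject, seeds_by_subject,
                              k_range = k_range, n_perm = n_perm,
                              alpha = alpha, rng_seed = rng_seed)
  sil <- vapply(sols, function(sol) silhouette_mean(parcellation$distance, sol), numeric(1))
  wss <- wss_curve(parcellation$group_z, sols)
  elbow <- elbow_point(wss)
  sil_k <- silhouette_vote(sil)
  consensus <- consensus_k(fp$k, elbow$k, sil_k)
  structure(
    list(solutions = sols, fingerprint = fp, silhouette = sil, wss = wss,
         elbow = elbow, silhouette_k = sil_k,
         chosen_k = consensus$k, votes = consensus$votes,
         rationale = consensus$rationale),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n  ", x$rationale, "\n", sep = "")
  invisible(x)
}
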