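# Task-based characterization of the parcels: block-design construction,
# convolution with MION/BOLD impulse responses, per-run GLM fitting with
# nuisance regressors, and percent-signal-change ROI statistics with
# one-tailed t-tests and Benjamini-Hochberg FDR correction.

#' Build a block design from an ordered block list
#'
#' Lays out the given sequence of blocks (repeated `repeats` times) after the
#' start volumes, producing an event table in seconds. When the printed run
#' length of an experiment cannot be reconstructed from its stated blocks,
#' `n_volumes` can be given explicitly; the builder then validates that the
#' events fit and records the discrepancy.
#'
#' @param blocks Data frame with columns `condition` and `duration_s`, in
#'   presentation order (may be empty).
#' @param tr_seconds Repetition time in seconds.
#' @param start_volumes Number of lead-in volumes before the first block.
#' @param repeats How many times the block sequence is presented per run.
#' @param n_volumes Optional explicit run length in volumes.
#' @return A `block_design`: list with `conditions`, `events` (condition,
#'   onset_s, duration_s), `tr_seconds`, `n_volumes`, `start_volumes`, and
#'   `length_discrepancy` (volumes by which the stated blocks under-fill an
#'   explicit `n_volumes`, 0 otherwise).
#' @export
build_block_design <- function(blocks, tr_seconds, start_volumes = 0L,
                               repeats = 1L, n_volumes = NULL) {
  stopifnot(is.data.frame(blocks) || is.null(blocks), tr_seconds > 0)
  if (is.null(blocks)) blocks <- data.frame(condition = character(0), duration_s = numeric(0))
  assert_count(start_volumes, "start_volumes", min = 0L)
  assert_count(repeats, "repeats")
  if (nrow(blocks) > 0 && any(blocks$duration_s %% tr_seconds != 0)) {
    bad <- which(blocks$duration_s %% tr_seconds != 0)[1L]
    stop(sprintf("block %d duration (%g s) is not divisible by TR (%g s)",
                 bad, blocks$duration_s[bad], tr_seconds))
  }
  seq_dur <- sum(blocks$duration_s)
  onsets <- numeric(0); conds <- character(0); durs <- numeric(0)
  t0 <- start_volumes * tr_seconds
  for (rep in seq_len(if (nrow(blocks)) repeats else 0L)) {
    for (b in seq_len(nrow(blocks))) {
      onsets <- c(onsets, t0); conds <- c(conds, blocks$condition[b])
      durs <- c(durs, blocks$duration_s[b])
      t0 <- t0 + blocks$duration_s[b]
    }
  }
  implied <- start_volumes + if (nrow(blocks)) repeats * seq_dur / tr_seconds else 0
  discrepancy <- 0
  if (is.null(n_volumes)) {
    n_volumes <- implied
  } else {
    assert_count(n_volumes, "n_volumes")
    if (implied > n_volumes) {
      stop(sprintf("stated blocks need %d volumes but n_volumes = %d", implied, n_volumes))
    }
    discrepancy <- n_volumes - implied
  }
  structure(
    list(conditions = unique(blocks$condition),
         events = data.frame(condition = conds, onset_s = onsets, duration_s = durs,
                             stringsAsFactors = FALSE),
         tr_seconds = tr_seconds, n_volumes = as.integer(n_volumes),
         start_volumes = as.integer(start_volumes),
         length_discrepancy = as.integer(discrepancy)),
    class = "block_design"
  )
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design: %d volumes @ TR %gs, %d events, conditions: %s>\n",
              x$n_volumes, x$tr_seconds, nrow(x$events),
              paste(x$conditions, collapse = ", ")))
  invisible(x)
}

# Impulse responses sampled at `dt` seconds over `length_s` seconds.
# BOLD: canonical double-gamma (peak ~5 s, undershoot ~15 s).
# MION: slower gamma-variate (shape 3, scale 3 s -> mode 6 s), sign-inverted
# because the iron-oxide contrast agent makes activation DECREASE the signal.
hrf_kernel <- function(hrf_kind, dt, length_s = 40,
                       mion_shape = 3, mion_scale = 3) {
  t <- seq(0, length_s, by = dt)
  h <- switch(hrf_kind,
    BOLD = stats::dgamma(t, shape = 6, rate = 1) -
           stats::dgamma(t, shape = 16, rate = 1) / 6,
    MION = -stats::dgamma(t, shape = mion_shape, scale = mion_scale),
    stop("unknown hrf_kind: ", hrf_kind, " (use \"MION\" or \"BOLD\")")
  )
  h
}

#' Convolved condition regressors for a block design
#'
#' One boxcar per condition, convolved with the chosen impulse response and
#' sampled at the TR. For MION the raw convolved shape is negative
#' (contrast-agent signal decrease); with `convention_flip = TRUE` (default)
#' regressors are sign-flipped so condition betas remain
#' positive-for-activation. Each column carries its peak value (the MarsBaR
#' scaling constant) in the `"peaks"` attribute.
#'
#' @param design A `block_design`.
#' @param hrf_kind `"MION"` or `"BOLD"`.
#' @param conditions Conditions to model (default: all in the design).
#' @param convention_flip Flip MION regressors to positive (default TRUE).
#' @param ... Passed to the kernel (e.g. `mion_shape`, `mion_scale`).
#' @return Matrix n_volumes x conditions with attributes `peaks` (per-column
#'   max after the convention flip) and `raw_sign` (-1 for MION, +1 for BOLD).
#' @export
hrf_regressors <- function(design, hrf_kind = c("MION", "BOLD"),
                           conditions = NULL, convention_flip = TRUE, ...) {
  stopifnot(inherits(design, "block_design"))
  hrf_kind <- match.arg(hrf_kind)
  if (is.null(conditions)) conditions <- design$conditions
  dt <- design$tr_seconds
  h <- hrf_kernel(hrf_kind, dt, ...)
  raw_sign <- if (hrf_kind == "MION") -1 else 1
  tvol <- (seq_len(design$n_volumes) - 1L) * dt
  X <- vapply(conditions, function(cond) {
    ev <- design$events[design$events$condition == cond, , drop = FALSE]
    box <- rep(0, design$n_volumes)
    for (e in seq_len(nrow(ev))) {
      # a volume is "on" when its acquisition time falls inside the block
      on <- tvol >= ev$onset_s[e] & tvol < ev$onset_s[e] + ev$duration_s[e]
      box[on] <- 1
    }
    reg <- stats::convolve(box, rev(h), type = "open")[seq_len(design$n_volumes)] * dt
    if (convention_flip && raw_sign < 0) -reg else reg
  }, numeric(design$n_volumes))
  colnames(X) <- conditions
  structure(X, peaks = apply(X, 2L, max), raw_sign = raw_sign)
}

#' Fit a per-run GLM
#'
#' Ordinary least squares of each voxel (or ROI-mean) time course against the
#' stacked design \[condition regressors | nuisance | intercept\].
#'
#' @param y Numeric vector (one ROI-mean time course) or matrix
#'   voxels x time.
#' @param regressors Convolved condition matrix from [hrf_regressors()].
#' @param nuisance Optional time x q nuisance matrix (e.g. six motion, two
#'   eye-position and one pupil regressor).
#' @return A `glm_fit`: list with `betas` (regressor x voxel matrix, the
#'   intercept last), `condition_names`, `peaks`, `residual_variance` (per
#'   voxel), `df_residual`, `xtx_inv`.
#' @export
fit_glm <- function(y, regressors, nuisance = NULL) {
  Y <- if (is.matrix(y)) t(y) else matrix(y, ncol = 1L)  # time x voxels
  n <- nrow(Y)
  if (nrow(regressors) != n) stop("regressor rows must equal time points")
  if (is.null(nuisance)) nuisance <- matrix(numeric(0), n, 0L)
  if (nrow(nuisance) != n) stop("nuisance rows must equal time points")
  nuis_names <- if (ncol(nuisance)) paste0("nuis", seq_len(ncol(nuisance))) else character(0)
  X <- cbind(regressors, nuisance, intercept = 1)
  colnames(X) <- c(colnames(regressors), nuis_names, "intercept")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  betas <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / max(df, 1L)
  inv_pivoted <- chol2inv(qr.R(qrX))
  xtx_inv <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  xtx_inv[qrX$pivot, qrX$pivot] <- inv_pivoted
  structure(
    list(betas = betas, condition_names = colnames(regressors),
         peaks = attr(regressors, "peaks"),
         residual_variance = sigma2, df_residual = df,
         xtx_inv = xtx_inv),
    class = "glm_fit"
  )
}

#' Percent signal change of a condition against its control
#'
#' MarsBaR-style scaling: `100 * (beta_condition - beta_control) * peak /
#' beta_intercept`, where `peak` is the maximum of the unit-amplitude
#' convolved block regressor, so a planted effect of e% is recovered as e.
#'
#' @param fit A `glm_fit` (one run; one or more voxels).
#' @param condition Condition of interest.
#' @param control Low-level control condition, or `NULL` for the implicit
#'   baseline (control beta 0).
#' @return Percent signal change (scalar, or vector over voxels).
#' @export
percent_signal_change <- function(fit, condition, control = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!condition %in% fit$condition_names) stop("unknown condition: ", condition)
  b_cond <- fit$betas[condition, ]
  b_ctrl <- if (is.null(control)) 0 else {
    if (!control %in% fit$condition_names) stop("unknown control: ", control)
    fit$betas[control, ]
  }
  b0 <- fit$betas["intercept", ]
  if (any(b0 <= 0)) stop("nonpositive baseline (intercept) beta: nonphysical")
  peak <- fit$peaks[[condition]]
  unname(100 * (b_cond - b_ctrl) * peak / b0)
}

#' Restrict an ROI to task-responsive voxels
#'
#' Keeps the ROI voxels whose mean response over the given conditions
#' (against the implicit fixation baseline) is significant in a one-tailed
#' voxelwise t-test on the supplied fit.
#'
#' @param fit A voxelwise `glm_fit` over the ROI's voxels.
#' @param conditions Conditions defining responsiveness (averaged contrast).
#' @param p_threshold One-tailed uncorrected threshold (default 0.05).
#' @return List: `keep` (logical per voxel), `t`, `p`, `empty` flag (TRUE with
#'   a warning when no voxel survives; downstream stats must skip the ROI).
#' @export
select_responsive_voxels <- function(fit, conditions, p_threshold = 0.05) {
  stopifnot(inherits(fit, "glm_fit"))
  cvec <- rep(0, nrow(fit$betas))
  names(cvec) <- rownames(fit$betas)
  cvec[conditions] <- 1 / length(conditions)
  effect <- drop(crossprod(cvec, fit$betas))
  se <- sqrt(fit$residual_variance * drop(t(cvec) %*% fit$xtx_inv %*% cvec))
  tval <- effect / se
  p <- stats::pt(tval, df = fit$df_residual, lower.tail = FALSE)
  keep <- p < p_threshold
  if (!any(keep)) warning("no responsive voxel in ROI; marking ROI empty")
  list(keep = keep, t = tval, p = p, empty = !any(keep))
}

#' Per-ROI percent-signal-change statistics with FDR correction
#'
#' One-sample one-tailed t-test (H1: mean PSC > 0) on the per-run PSC values
#' of each ROI, with Benjamini-Hochberg adjustment across the ROIs of one
#' cluster solution. Both raw and adjusted p-values are reported.
#'
#' @param psc_by_roi Named list: ROI -> numeric vector of per-run PSC values
#'   (>= 2 runs each).
#' @param alpha Significance level for the flag (default 0.05, on p_fdr).
#' @return Data frame: roi, n_runs, mean, sem, t, p_raw, p_fdr, significant.
#' @export
psc_ttest_fdr <- function(psc_by_roi, alpha = 0.05) {
  stopifnot(is.list(psc_by_roi), length(psc_by_roi) >= 1L)
  rows <- lapply(names(psc_by_roi), function(roi) {
    x <- psc_by_roi[[roi]]
    if (length(x) < 2L) stop("ROI ", roi, ": need >= 2 runs for a t-test")
    m <- mean(x); sem <- stats::sd(x) / sqrt(length(x))
    tval <- if (sem == 0) { if (m == 0) 0 else sign(m) * Inf } else m / sem
    p <- stats::pt(tval, df = length(x) - 1L, lower.tail = FALSE)
    data.frame(roi = roi, n_runs = length(x), mean = m, sem = sem,
               t = tval, p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_fdr < alpha
  out
}
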