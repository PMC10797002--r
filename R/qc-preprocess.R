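# Run-level quality control and per-run signal conditioning. Everything
# downstream (connectivity, fingerprints, seed-to-brain maps) consumes runs
# that have passed these filters and been bandpassed + nuisance-regressed.

#' Construct a voxel time-series run
#'
#' Bundles one run's mask-voxel time series with its nuisance regressors and
#' metadata. This is the unit of data every preprocessing and connectivity
#' operation consumes.
#'
#' @param data Numeric matrix, voxels x time points.
#' @param nuisance Numeric matrix, time points x q (e.g. white-matter mean,
#'   ventricle mean, and six head-motion parameters). May have zero columns.
#' @param tr_seconds Repetition time in seconds (sampling interval).
#' @param subject_id,run_id Identifier strings.
#' @param fixation_fraction Fraction of the run spent fixating, in \[0, 1\],
#'   or `NA` when eye tracking is unavailable.
#' @return An object of class `voxel_run`.
#' @export
voxel_run <- function(data, nuisance = NULL, tr_seconds = 2,
                      subject_id = "S1", run_id = "R1",
                      fixation_fraction = NA_real_) {
  data <- as.matrix(data)
  if (nrow(data) < 2L || ncol(data) < 8L) {
    stop("run data must have >= 2 voxels and >= 8 time points")
  }
  if (is.null(nuisance)) {
    nuisance <- matrix(numeric(0), nrow = ncol(data), ncol = 0L)
  }
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != ncol(data)) {
    stop("nuisance rows must equal the number of time points in `data`")
  }
  if (!is.na(fixation_fraction)) assert_prob(fixation_fraction, "fixation_fraction")
  stopifnot(tr_seconds > 0)
  structure(
    list(data = data, nuisance = nuisance, tr_seconds = tr_seconds,
         subject_id = as.character(subject_id), run_id = as.character(run_id),
         fixation_fraction = as.numeric(fixation_fraction)),
    class = "voxel_run"
  )
}

#' @export
print.voxel_run <- function(x, ...) {
  cat(sprintf("<voxel_run %s/%s: %d voxels x %d volumes, TR %gs, fixation %s, %d nuisance>\n",
              x$subject_id, x$run_id, nrow(x$data), ncol(x$data), x$tr_seconds,
              ifelse(is.na(x$fixation_fraction), "NA",
                     sprintf("%.0f%%", 100 * x$fixation_fraction)),
              ncol(x$nuisance)))
  invisible(x)
}

#' Exclude runs with poor fixation
#'
#' Retains runs whose fixation fraction is at or above `threshold`; runs
#' strictly below are excluded ("below 85%" excludes, so exactly 85% is
#' retained).
#'
#' @param runs List of [voxel_run] objects.
#' @param threshold Retention threshold as a proportion (default 0.85).
#' @return List with `retained` (runs) and `log` (data frame of run_id,
#'   fixation_fraction, retained flag, reason).
#' @export
filter_by_fixation <- function(runs, threshold = 0.85) {
  assert_prob(threshold, "threshold")
  frac <- vapply(runs, function(r) r$fixation_fraction, numeric(1))
  missing <- vapply(runs, function(r) is.na(r$fixation_fraction), logical(1))
  if (any(missing)) {
    bad <- vapply(runs[missing], function(r) r$run_id, character(1))
    stop("fixation_fraction missing for run(s): ", paste(bad, collapse = ", "))
  }
  keep <- frac >= threshold
  log <- data.frame(
    run_id = vapply(runs, function(r) r$run_id, character(1)),
    subject_id = vapply(runs, function(r) r$subject_id, character(1)),
    fixation_fraction = frac,
    retained = keep,
    reason = ifelse(keep, "", sprintf("fixation %.3f below threshold %.3f", frac, threshold)),
    stringsAsFactors = FALSE
  )
  list(retained = runs[keep], log = log)
}

# Per-run QC statistic: mean of all pairwise voxel Pearson correlations
# (upper triangle). Errors on constant voxels, whose correlation is undefined.
run_mean_correlation <- function(run) {
  sds <- apply(run$data, 1L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant voxel time series (voxel %d) in run %s: correlation undefined",
                 which(sds == 0)[1L], run$run_id))
  }
  cm <- stats::cor(t(run$data))
  mean(cm[upper.tri(cm)])
}

#' Exclude runs whose mean voxel correlation is a median outlier
#'
#' For each run the average of all pairwise voxel correlations is computed;
#' runs outside `[median/2, 2 * median]` across runs are excluded as outliers.
#'
#' @param runs List of [voxel_run] objects (at least 3, so the median has
#'   support).
#' @param statistic Either `"pairwise"` (mean of all pairwise voxel
#'   correlations, the default) or `"to_mean"` (mean correlation of each voxel
#'   with the global mean time course) — two readings of the same QC rule.
#' @return List with `retained`, `log` (run_id, statistic value, bounds,
#'   retained flag, reason).
#' @export
filter_by_mean_correlation <- function(runs, statistic = c("pairwise", "to_mean")) {
  statistic <- match.arg(statistic)
  if (length(runs) < 3L) stop("need >= 3 runs for the median-based outlier rule")
  stat <- vapply(runs, function(r) {
    if (statistic == "pairwise") {
      run_mean_correlation(r)
    } else {
      gm <- colMeans(r$data)
      mean(stats::cor(t(r$data), gm))
    }
  }, numeric(1))
  m <- stats::median(stat)
  lo <- m / 2; hi <- 2 * m
  keep <- stat >= lo & stat <= hi
  log <- data.frame(
    run_id = vapply(runs, function(r) r$run_id, character(1)),
    subject_id = vapply(runs, function(r) r$subject_id, character(1)),
    mean_correlation = stat,
    median = m, lower = lo, upper = hi,
    retained = keep,
    reason = ifelse(keep, "",
                    sprintf("mean correlation %.4f outside [%.4f, %.4f]", stat, lo, hi)),
    stringsAsFactors = FALSE
  )
  list(retained = runs[keep], log = log)
}

# Zero-phase bandpass gain profile: the squared magnitude response of an
# order-`order` Butterworth band-pass, i.e. what forward-backward filtering
# applies. Computed per FFT bin; the DC bin is zeroed outright.
butterworth_gain <- function(freq_hz, low_hz, high_hz, order) {
  lp <- 1 / (1 + (freq_hz / high_hz)^(2 * order))
  hp <- ifelse(freq_hz == 0, 0, 1 / (1 + (low_hz / freq_hz)^(2 * order)))
  lp * hp
}

# Filter the rows of a time x series matrix (columns are independent series).
bandpass_matrix <- function(x, tr_seconds, low_hz, high_hz, order) {
  n <- nrow(x)
  freq <- c(0, seq_len(n - 1)) / (n * tr_seconds)
  freq <- pmin(freq, 1 / tr_seconds - freq)  # fold to two-sided spectrum
  gain <- butterworth_gain(freq, low_hz, high_hz, order)
  xf <- stats::mvfft(x)
  Re(stats::mvfft(xf * gain, inverse = TRUE)) / n
}

#' Zero-phase bandpass filter a run
#'
#' Applies a zero-phase band-pass (squared Butterworth magnitude response,
#' applied in the frequency domain) to every voxel and every nuisance column.
#' The DC component is removed exactly.
#'
#' @param run A [voxel_run].
#' @param low_hz,high_hz Pass-band edges in Hz (defaults 0.0025 and 0.05, the
#'   infra-slow band used for resting-state parcellation).
#' @param order Butterworth order of the underlying one-pass filter
#'   (default 4).
#' @return A filtered [voxel_run] of identical shape.
#' @export
bandpass <- function(run, low_hz = 0.0025, high_hz = 0.05, order = 4) {
  stopifnot(inherits(run, "voxel_run"))
  nyquist <- 1 / (2 * run$tr_seconds)
  if (high_hz >= nyquist) {
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency %g Hz", high_hz, nyquist))
  }
  if (low_hz >= high_hz) stop("low_hz must be below high_hz")
  run$data <- t(bandpass_matrix(t(run$data), run$tr_seconds, low_hz, high_hz, order))
  if (ncol(run$nuisance) > 0L) {
    run$nuisance <- bandpass_matrix(run$nuisance, run$tr_seconds, low_hz, high_hz, order)
  }
  run
}

#' Regress nuisance series out of every voxel
#'
#' Ordinary least-squares residual of each voxel time series against an
#' intercept plus the run's nuisance columns (white matter, ventricles, head
#' motion). Residuals are exactly orthogonal to every nuisance column, so a
#' subsequent plain correlation equals the partial correlation controlling for
#' the nuisance set.
#'
#' @param run A [voxel_run].
#' @return Numeric matrix of residuals, voxels x time.
#' @export
regress_nuisance <- function(run) {
  stopifnot(inherits(run, "voxel_run"))
  X <- cbind(intercept = 1, run$nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop("nuisance matrix is rank deficient; collinear column(s): ",
         paste(dropped - 1L, collapse = ", "))
  }
  t(qr.resid(qrX, t(run$data)))
}
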