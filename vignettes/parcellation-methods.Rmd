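---
title: "Methods: connectivity-based parcellation and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based parcellation and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the model it implements, the
parameters that matter, the numerical decisions taken where the method left
room, and what the synthetic-data tests do and do not establish. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

The pipeline treats a masked set of voxels as exchangeable items whose
identity is their *connectivity profile*: the vector of Fisher-z partial
correlations with every other mask voxel, estimated per run, averaged runs →
subject → group. Two modelling commitments follow:

* **Partial correlation means nuisance-controlled pairwise correlation.**
  Every voxel is OLS-regressed on an intercept plus the nuisance set
  (white-matter mean, ventricle mean, six head-motion parameters) and
  correlations are taken between residuals. This equals the textbook partial
  correlation controlling for that set (verified against the precision-matrix
  formula in the tests). It is *not* the full-mask precision matrix: with
  ~300 time points and hundreds-to-thousands of voxels that inverse is
  singular, and the analysis names only the nuisance series as controlled
  variables.
* **Two-stage averaging weights subjects equally.** z-matrices are averaged
  across runs within subject first, then across subjects, so a subject with
  19 retained runs counts the same as one with 14.

Clustering is unweighted average linkage (UPGMA) on the pairwise Euclidean
distance between profile rows. UPGMA is reducible, so merge heights are
monotone and cutting the K and K+1 solutions from one tree is always
nested — a property the validation criteria rely on and the tests assert.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `low_hz`, `high_hz` | 0.0025, 0.05 | Hz | infra-slow band in which resting-state coupling concentrates; also the band of the generator's latent signals |
| `filter_order` | 4 | – | Butterworth order of the zero-phase filter |
| `fixation_threshold` | 0.85 | proportion | runs below are excluded; exactly 0.85 is retained ("below" is strict) |
| outlier rule | [m/2, 2m] | – | m = median of per-run mean pairwise correlation; see below |
| `k_min..k_max` | 2..10 | clusters | exploratory range of solutions |
| `n_perm` | 100000 | iterations | permutation budget; exact enumeration substitutes when `2^subjects <= n_perm` |
| `alpha` | 0.05 | – | pairwise fingerprint significance level |
| `z_threshold` | 2.3 | z units | seed-to-brain map threshold, strict `>` |
| `seed_radius_mm` | 2 | mm | seed sphere radius; 33 voxels on a 1 mm grid |
| `hrf_kind` | MION | – | contrast-agent response, sign-inverted relative to BOLD |

## Numerical decisions

**Bandpass filter.** The specification of a "4th-order zero-phase
Butterworth" is realized in the frequency domain: each series is FFT'd,
multiplied by the *squared* Butterworth magnitude response (what a
forward–backward time-domain pass applies), and inverted; the DC bin is
zeroed outright. No time-domain IIR filtering package is among the package's
dependencies, and the frequency-domain form is exactly zero-phase, exactly
DC-free, and has the designed gain at every bin (≥ 0.999 at 0.02 Hz, ≤ 1.6e-5
at 0.2 Hz for the default band at TR 2 s — the tests assert the looser 0.9 /
0.1 bounds). The difference from `filtfilt` is confined to edge transients;
circular wrap-around is immaterial for zero-mean stationary series of ≥ 300
samples.

**Fisher transform clipping.** `atanh` is applied after clipping |r| to
`1 − 1e-7`, keeping z finite (≈ 8.4) at machine-level cost: the clip is far
below the resolving power of any r estimated from ≤ 300 samples.

**Diagonal convention.** The self-correlation z (infinite before clipping)
is replaced by 0 in the group matrix before row distances are taken. Any
constant would do; 0 keeps rows comparable. This changes each pairwise
distance slightly relative to dropping the two self-entries, identically for
all pairs.

**UPGMA tie-break.** Among tied minimum-distance pairs the pair with the
lexicographically smallest (creation-order) index is merged, leaves ranked
before internal nodes. MATLAB-style toolboxes leave this unspecified; fixing
it makes dendrograms bit-reproducible, and the O(n³) brute-force oracle in
the tests implements the same rule independently.

**Permutation test.** The exchange null swaps the two clusters' fingerprints
within each subject independently (probability ½ each) — the natural
exchangeable null for "shuffling the pairwise cluster labels per subject".
When `2^subjects ≤ n_perm` the full set is enumerated and the p-value is
exact (`#{cosine ≤ observed}/2^n`); otherwise Monte-Carlo sampling with the
add-one correction `p = (1 + #{≤ obs})/(1 + n_perm)` keeps p > 0.
Normalization happens *after* across-subject averaging inside every
iteration, in the stated order average → normalize → cosine. Two structural
facts worth knowing:

* complementary swap patterns give identical cosines, so the smallest
  attainable exact p is `2/2^n`; at α = 0.05 the criterion is only reachable
  with **≥ 6 subjects** (with the default 8, min p = 2/256 ≈ 0.0078);
* at 8 subjects the achievable test size at p < 0.05 is 12/256 ≈ 0.0469 —
  slightly conservative, and the measured type-I error in the acceptance run
  sits there, inside the binomial 95% interval around 0.05.

**Constant fingerprints.** A constant group-mean fingerprint (max = min)
min-max-normalizes to all 0.5 rather than erroring, keeping the cosine
defined and comparable.

**Elbow.** The elbow is the K maximizing the discrete second difference
`WSS(K−1) − 2·WSS(K) + WSS(K+1)` over interior K. A curve with (numerically)
constant second differences has no elbow: the smallest interior K is
returned with a warning rather than a fabricated optimum.

**Silhouette vote.** The silhouette's vote in the consensus is the highest
interior local peak (a K whose mean silhouette exceeds both neighbours),
falling back to the global argmax when no interior peak exists. Singleton
clusters contribute s = 0.

**Consensus.** Majority among {fingerprint, elbow, silhouette}; a three-way
split defers to the fingerprint criterion as the only inferential one.

**Fixed effects.** "Fixed-effects combination" of per-run z-maps is
Stouffer's `Σz/√N` (plain averaging is available behind a switch; it changes
scale, not ranking). Runs are pooled flat across subjects by default.

**Percent signal change.** MarsBaR-style scaling:
`100·(β_cond − β_ctrl)·peak/β_intercept`, where `peak` is the maximum of the
unit-amplitude convolved block regressor. The task generator plants effects
through unit-peak regressors, so a planted e% is recovered as e exactly in
the noise-free limit (asserted to 1e-6).

**MION kernel.** The MION impulse response is a gamma-variate (shape 3,
scale 3 s → mode at 6 s, slow tail), sign-inverted because the contrast
agent makes activation *decrease* the signal; regressors are convention-
flipped so condition betas stay positive-for-activation. No specific kernel
is canonical in the literature; the parameters are arguments, so
alternatives are drop-in. The BOLD kernel is the canonical double gamma.

**Designs that don't reconstruct.** The facial-expression (185 volumes) and
grasping (305) designs rebuild exactly from their stated blocks; these are
the asserted worked examples. The taste (185), distaste (240) and vestibular
(145) run lengths cannot be reconstructed from their stated blocks alone, so
those builders take the printed length explicitly, validate that the events
fit, and record the gap in `length_discrepancy`.

**Outlier rule reading.** "Values below or above two times the median" is
read symmetrically as outside `[median/2, 2·median]`; the per-run statistic
and both bounds are written to the QC log so the alternative (one-sided)
reading can be audited from the artifacts. The statistic is the mean of all
pairwise voxel correlations; a variant using each voxel's correlation with
the global mean time course is available (`statistic = "to_mean"`).

**I/O formats.** Artifacts are plain text: CSV/TSV matrices, YAML
configuration, JSON manifests/reports, Newick dendrograms. Grid geometry
(dimensions + 4×4 affine) travels in the manifest, and seed spheres are
resolved against that geometry directly, so no imaging-format library is
required; voxel ordering is the column-major scan of the mask volume with
0-based flat indices, recorded in the manifest.

## The synthetic world

`generate_rest_dataset()` emulates exactly the structure the analysis
assumes, with defaults stating the emulated acquisition: 8 subjects × 3 runs
× 300 volumes at TR 2 s, 100 mask voxels (60 in the time-boxed acceptance
runs), 4 planted communities, 23 external seeds, community SNR 2, nuisance
amplitude 0.5, baseline 1000.

* Community latents are Gaussian processes band-limited to 0.0025–0.05 Hz —
  the pipeline's own pass-band — so filtering is structure-preserving.
* A voxel of community c emits `snr·L_c(t)` plus nuisance leakage
  (white-matter/ventricle AR(1) series with per-voxel uniform weights) plus
  unit white noise; seeds emit `Σ_c mixing[c,s]·L_c(t)` plus noise. The
  default mixing gives each community a strongly-driven block of seeds
  (weight 1 vs 0.1), making fingerprints distinct.
* Communities are contiguous blocks in a 1-D voxel ordering: the clustering
  itself uses no spatial term, so contiguity is only a stand-in for mask
  geometry and a visualization aid.
* Fixation fractions are drawn uniformly in [0.85, 1]: the stated world is a
  well-trained cohort in which the fixation filter excludes nothing; the
  filter's behaviour is exercised separately with explicit fractions.

Not emulated: scanner artifacts, spatially structured noise, motion-induced
displacement, physiological aliasing, inter-subject anatomical variability,
distance-dependent correlation structure. A green planted-recovery test
therefore establishes that the pipeline's estimator-chain is correct and
well-conditioned at realistic SNR — not that the method resolves arbitrary
real-data parcellations; with real data the choice of K rests on the three
criteria, whose disagreement the consensus rule adjudicates.

The null-fingerprint generator draws both clusters' per-subject fingerprints
i.i.d. around one shared mean profile (noise sd 0.2), which is precisely the
exchangeability null of the permutation test — hence its use for type-I
calibration.

## Known limitations

* The fingerprint criterion's resolution is bounded by the subject count
  (min p = `2/2^n`); below 6 subjects it cannot reject at α = 0.05 and the
  consensus then rests on the two descriptive criteria.
* Pairwise fingerprint tests are not corrected for the K(K−1)/2 comparisons
  (deliberately, matching the source analysis); the criterion's "largest
  all-significant K" is therefore mildly anti-conservative for large K
  ranges.
* Seed-to-brain maps use no cluster-extent or multiple-comparison
  correction beyond the z > 2.3 threshold.
* The frequency-domain filter assumes approximately stationary, detrended
  series; strong slow drifts alias into the pass-band edges (the DC bin
  removal handles only the mean).
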