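Package: rsparcel
Title: Connectivity-Based Parcellation of Resting-State fMRI Voxel Masks
Version: 1.0.0
Authors@R:
    person("rsparcel", "maintainers", email = "rsparcel@example.org", role = c("aut", "cre"))
Description: A tested pipeline for parcellating a voxel mask from resting-state
    fMRI functional connectivity: run-level quality control (fixation and
    mean-correlation filters), zero-phase bandpass filtering and nuisance
    regression, voxelwise partial-correlation connectivity with Fisher
    z-transformation and two-stage group averaging, unweighted average-linkage
    (UPGMA) hierarchical clustering with 2- to 10-cluster solutions, three
    cluster-validation criteria (seed-fingerprint cosine-similarity permutation
    tests, mean silhouette, within-cluster sum-of-squares elbow), seed-to-brain
    fixed-effects connectivity maps, and task-based region-of-interest percent
    signal change statistics with one-tailed t-tests and false-discovery-rate
    correction. Includes a synthetic-data generator with planted community
    structure for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
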