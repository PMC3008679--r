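Package: restgca
Title: Seed-Based Granger Causality Mapping for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Directed (effective) connectivity analysis of resting-state BOLD
    fMRI from a seed region. Implements nuisance preprocessing (initial volume
    discarding, head-motion summary and exclusion, motion/white-matter/CSF
    regression, 0.01-0.08 Hz band-pass filtering, linear detrending, optional
    Gaussian smoothing), bivariate lag-1 Granger causality with Geweke's
    influence measure in both directions, Schwarz-criterion model-order
    selection, permutation null distributions, group mapping with
    Benjamini-Hochberg false discovery rate control and cluster-extent
    filtering, two-sample group contrasts, and post-hoc cluster-clinical
    Pearson correlations. A vector-autoregressive phantom generator produces
    fully synthetic cohorts (4D volumes, masks, motion traces, clinical
    scores) so every stage of the pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
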