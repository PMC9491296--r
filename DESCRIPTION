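Package: nlfnc
Title: Explicitly Nonlinear Functional Network Connectivity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates explicitly nonlinear functional network connectivity
    (FNC) among component time courses, such as ICA-derived intrinsic
    connectivity networks from resting-state fMRI. The linear dependence
    between each pair of time courses is removed by ordinary least-squares
    regression and the residual dependence is quantified with normalized
    mutual information (NMI) from a histogram plug-in entropy estimator,
    symmetrized over the two regression directions. A "boosted" metric
    combines the Pearson correlation with the sign-aligned nonlinear NMI.
    Includes simulators for validation cases and multi-subject cohorts with
    controlled linear and quadratic couplings, per-subject connectivity
    matrix construction, group averaging, minimum-cell and two-sample group
    comparisons with Benjamini-Hochberg false discovery rate control,
    permutation block-modularity assessment, joint-distribution difference
    maps, and amplitude spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
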