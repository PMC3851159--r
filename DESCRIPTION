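Package: rehopipe
Title: Regional Homogeneity Analysis of Resting-State fMRI Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise regional homogeneity (ReHo) analysis for resting-state
    BOLD fMRI. Computes Kendall's coefficient of concordance over cubic voxel
    neighborhoods, standardizes subject maps, performs covariate-adjusted
    voxel-wise two-sample t-tests between groups, and controls family-wise
    error with Monte-Carlo (AlphaSim-style) cluster-extent thresholds.
    Includes the post-alignment preprocessing chain (initial volume
    discarding, head-motion quality control, Gaussian spatial smoothing,
    linear detrending, band-pass filtering) and a synthetic BOLD cohort
    generator with controllable regional synchrony for ground-truth
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Preprocessing, Visualization
RoxygenNote: 7.3.3
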