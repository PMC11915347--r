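Package: neoconn
Title: Grey-Matter Microstructural and Functional Connectivity Co-Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how grey-matter microstructural connectivity (MC,
    a structural-covariance-style measure built from regional diffusion-metric
    fingerprints) and resting-state functional connectivity (FC) co-develop in
    neonatal cohorts. Builds group-wise MC matrices via confound residualization,
    min-max scaling, fingerprint concatenation and Pearson correlation; builds
    subject- and group-level FC matrices from ROI BOLD time series; computes
    longitudinal change matrices (a difference of absolute MC, and a
    confidence-interval-overlap-weighted FC difference); provides edge-level
    statistics (Huber robust regression with permutation-tested slopes, paired
    Wilcoxon tests, slope Z-comparisons, Benjamini-Hochberg correction,
    top-fraction thresholding); and quantifies network overlap by Ward
    hierarchical clustering with mutual information across all cluster-size
    pairs against permutation nulls. A synthetic cohort generator with planted
    block structure, confound effects and longitudinal pairing makes the whole
    pipeline testable without access to the original imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
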