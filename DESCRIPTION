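Package: fdgdecline
Title: Biomarker Thresholds Predictive of Imminent Metabolic Decline in
    Preclinical Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating amyloid-PET and CSF p-tau thresholds that
    predict imminent decline in brain glucose metabolism, and for planning
    enriched clinical trials on that basis. Implements the annualized
    percent-change statistic for longitudinal FDG-PET SUVR, supra-threshold
    mean-change curves with four-parameter sigmoid fitting and AICc model
    selection (the inflection of the preferred sigmoid is read as the
    imminent-decline threshold), an exhaustive two-biomarker threshold grid,
    voxel-wise and region-of-interest per-arm sample-size (power) mapping
    with FDR-masked decline maps, covariate-adjusted group contrasts, and a
    seeded synthetic cohort generator that emulates the stratified biomarker
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
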