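Package: stepup
Title: Segmental Treatment Planning and Trial Statistics for Staged
    Bronchoscopic Lung Volume Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-CT treatment planning for staged, bilateral,
    segmental bronchoscopic lung volume reduction in upper-lobe predominant
    emphysema, together with the supporting clinical-trial machinery.
    Computes per-segment tissue-to-air ratios (TAR) from voxel phantoms or
    densitometry tables, evaluates the segmental heterogeneity index,
    enumerates all bilateral treatment options, filters them against the
    per-session and combined volume windows, the 1700 ml per-session cap and
    the HI >= 1.2 criterion, and selects the preferred plan by combined TAR
    with target-volume tie-breaking, emitting a full constraint audit.
    Companion modules implement the eligibility screen, noncentral-t sample
    size with unequal allocation, the two-endpoint Hochberg decision rule,
    responder definitions, the missing-data imputation hierarchy,
    site-stratified blocked randomization, visit calendars, and a
    synthetic-data engine (virtual lungs, phantoms, cohorts, Monte-Carlo
    power checks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'densitometry.R'
    'phantom.R'
    'lung-model.R'
    'plan-options.R'
    'plan-select.R'
    'eligibility.R'
    'trial-stats.R'
    'trial-sim.R'
    'cli.R'
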