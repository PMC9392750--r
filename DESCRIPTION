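Package: tauhub
Title: Connectivity-Hub Weighted Analysis of Tau-PET Deposition Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify whether an individual's tau-PET deposition
    pattern is concentrated in globally connected brain hubs. Builds scaled
    hub maps from ROI-level functional connectivity (Fisher-z correlation,
    density thresholding, shortest-path distance, mean-distance degree),
    converts ROI tau-PET SUVRs to off-target-cleaned tau positivities with
    per-ROI Gaussian mixture models, estimates per-subject annual tau
    accumulation rates with linear mixed models, and computes the tau hub
    ratio together with its inferential battery: standardized-beta
    regressions, shuffled-connectome exact tests, sliding-window interaction
    analysis, and bootstrapped mediation. Includes a synthetic-cohort
    generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    mclust,
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
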