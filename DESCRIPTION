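Package: sitespec
Title: Site-Specific Cortical Bone Morphometry from Micro-CT Cross-Sections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-bone cortical morphometry for micro-CT image stacks of
    mouse long bones. Selects the cross-sectional slice at each 1% site along
    the bone, segments cortex and marrow by deterministic two-means intensity
    thresholding with largest-component fibula exclusion, and computes
    per-site cortical, marrow and total areas, mean cross-sectional thickness,
    principal second moments of area and the polar moment of inertia, Feret
    caliper diameters and eccentricity. Bone orientation is normalized to the
    Feret angle of a reference site and curvature is quantified as absolute
    centroid deviation from a straight central axis. Includes a
    surface-perturbation simulation of periosteal/endosteal remodelling
    effects on the polar moment of inertia, mixed-model site-by-intervention
    statistics with Bonferroni post hoc site maps and simulated power
    analysis, and a synthetic tibia-like phantom generator with analytic
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    tiff,
    EBImage,
    lme4,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, Visualization, Preprocessing
RoxygenNote: 7.3.3
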