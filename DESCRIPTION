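Package: spermHT
Title: Holotomographic Morphometry and Cryotolerance Analysis of Sperm Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of refractive-index (RI) tomograms
    of spermatozoa in cryopreservation studies. Segments 3D RI grids into
    sperm compartments (whole cell, post-acrosomal region and midpiece,
    nucleus) by fixed RI windows, computes per-region morphometry (volume,
    surface area, sphericity, projection area, dry mass, concentration),
    derives the holotomographic freezability index FI_HT as the post-freeze
    to fresh volume ratio, summarises CASA-style sperm kinematics (VCL, VSL,
    VAP, straightness, motility classes), and runs the accompanying
    statistical workflow (arcsine transform, assumption checks, ANOVA with
    Bonferroni pairwise comparisons). Includes synthetic phantom and track
    generators that emulate a donor-by-extender study design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    readr,
    ggplot2,
    jsonlite,
    rlang,
    tiff,
    car,
    stats,
    grDevices,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
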