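Package: rangetraits
Title: Effort-Controlled Range-Change Indices and Trait-Based Multimodel
    Inference for Atlas Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying species range changes from volunteer-
    collected atlas occurrence records and explaining them with species
    traits.  Occurrence records carrying Ordnance-Survey-style grid
    references are resolved to 10 km squares (hectads), recording effort is
    controlled by restricting comparisons to squares surveyed in both time
    periods, and per-species change is expressed both as a logit-difference
    ("uncorrected") index and as the standardized residual of a cross-species
    regression of later-period on earlier-period occupancy (the relative
    "Telfer" index, robust to overall changes in recorder effort).  The
    trait analysis screens the change vector for outliers with sequential
    Grubbs tests, pre-screens trait collinearity, fits Gaussian linear
    models for every non-empty trait subset, selects a top set by
    information-criterion difference, and averages coefficients, standard
    errors and fit statistics with Akaike weights.  Phylogenetic robustness
    checks (taxonomy-based working phylogeny, Moran's I on model residuals,
    Pagel's lambda generalized least squares) and a synthetic atlas-data
    generator for end-to-end validation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
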