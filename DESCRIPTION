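Package: hydrotraits
Title: Hydraulic-Trait-Based Analysis of Stomatal Regulation of Tree Sap Flux
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how stomatal conductance regulates tree sap flux
    density as atmospheric vapour pressure deficit rises, built around a
    mechanistic trait-based model linking stomatal conductance to sap flux
    through the Huber value (sapwood-to-leaf-area ratio). Fits per-tree
    parabolic and logarithmic sap-flux response curves and extracts the
    deficit at maximum flux, computes anatomical and functional hydraulic
    traits (Hagen-Poiseuille theoretical conductivity, anatomical maximum
    stomatal conductance, whole-plant hydraulic conductance, branch
    allometry, leaf vein density), calibrates conductance against the
    flux-to-deficit ratio, and provides the cross-species statistical layer
    (principal components, exact LMG relative-importance decomposition of R
    squared with bootstrap intervals, Tukey multiple comparisons). Includes a
    forward simulator of a multi-species field campaign with known
    ground-truth traits so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lmtest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
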