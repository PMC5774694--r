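Package: fermphen
Title: Fermentation Phenomics of Wine Yeast from Vial Weight-Loss Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for small-vial wine fermentation phenomics:
    converts manual weighing logs of fermenting grape must into smoothed
    CO2-release curves and six kinetic parameters (lag phase, t35/t50/t80,
    V50_80, CO2max), models end-point metabolite panels, decomposes trait
    variance into strain, must, micro-oxygenation and interaction terms with
    permutation ANOVA p-values and Tukey compact letter displays, and
    characterizes strain panels across grape musts by Spearman correlation,
    PCA, rank clustering and cross-environment robustness quartiles. Includes
    a factorial experiment simulator with the same additive effect structure
    for validation and power studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
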