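Package: cytosieve
Title: Filtration-Chromatography Proteomics of Biomolecular Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for filtration-chromatography ("sieving")
    proteomics of cytoplasm, built to quantify how much of a proteome is
    organized in mesoscale, liquid-like biomolecular condensates. Provides a
    forward simulator of pore-size- and dilution-dependent elution of free
    proteins, rigid complexes, deformable condensates and membrane-bound
    organelles; quantile normalization of multiplexed fold-change tables;
    squeezing scores from the upper edge of timepoint scatters; ROC/AUC and
    two-sample statistics against reference protein sets; an empirical
    replicate-noise null model with false-discovery-rate classification of
    liquid-like behavior and proteome composition estimates; a bagged
    tree/linear-discriminant ensemble that predicts phase-separating proteins
    from elution and sequence features; and size-exclusion bead metrics
    (accessible volume, fill fractions, step coefficient of variation,
    Stokes-Einstein radii).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
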