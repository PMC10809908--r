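Package: popclim
Title: Landscape Genomics of Local Adaptation: Diversity Scans,
    Genotype-Environment Association and Climate Maladaptation Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for landscape-genomics analyses of
    resequenced plant populations: VCF ingestion with standard site
    filters, windowed nucleotide diversity, Weir-Cockerham F_ST and
    Tajima's D, linkage-disequilibrium decay, PCA-based population
    structure, Mantel tests of isolation by distance and by environment,
    joint top-quantile F_ST x theta-pi-ratio selective-sweep scans with
    gene annotation, latent-factor genotype-environment association with
    genomic-inflation calibration, partial redundancy analysis
    conditioned on geography, and risk-of-non-adaptedness (RONA)
    projections under future climate scenarios.  A seeded synthetic-data
    generator with recorded ground truth makes every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    geosphere,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
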