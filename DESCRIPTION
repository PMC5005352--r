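Package: cellcarbon
Title: Biovolume and Carbon Content of Sub-Seafloor Microbial Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the size and biomass of microbial cells in
    deep marine sediments from tabulated microscopy measurements and
    cellular amino-acid analyses. Classifies cells into morphotypes
    (coccoid, elongated, filamentous), computes biovolumes under standard
    shape models (sphere, capsule, prolate spheroid, ellipsoid), applies a
    multiplicative correction cascade for sample-treatment artifacts
    (fixation shrinkage, filtration, the epifluorescence halo effect, and
    dehydration with critical point drying), converts total hydrolyzable
    amino acid (THAA) measurements into cell-specific carbon content and
    carbon density, and summarizes depth profiles with one-way ANOVA and
    bootstrap intervals. A synthetic-study generator with depth-declining
    lognormal cell volumes and modality-specific observation biases makes
    every stage of the pipeline testable without access to raw microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
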