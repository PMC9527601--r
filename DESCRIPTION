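Package: gsicross
Title: Gametophytic Self-Incompatibility Cross Prediction and S-Locus
    Analysis for Roses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genetic computations for S-RNase-based gametophytic
    self-incompatibility (GSI) in Rosa: pollen transmission with
    recombination and GSI acceptance filtering, cross compatibility
    classification and offspring prediction, pollen-genotype inference and
    segregation tests from seed genotype counts, recombination-fraction
    estimation from phased F1 populations, genetic-to-physical map
    regression, candidate S-RNase screening from tissue expression and
    allelic divergence, marker-based S/KSN/AP2 genotype calling with
    breeding-period introgression trends, and seeded synthetic-data
    generators for every input the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
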