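Package: tubulinvep
Title: Structural Classification and Variant Effect Predictor Benchmarking for Tubulin Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing missense variants in the human tubulin gene
    family. Provides curation and validation of pathogenic and putatively
    benign (gnomAD) variant catalogs, mapping of variant positions onto
    tubulin three-dimensional structures with hierarchical classification of
    structural locations (GTP-binding site, intradimer interface, MAP
    interface, microtubule lattice contacts, buried interior, surface),
    location-enrichment testing, group comparisons of predicted folding
    stability changes, ROC/AUC benchmarking of variant effect predictor
    score tables with phenotype stratification and native-scale optimal
    thresholds, and a mean cumulative distribution (MCD) score for ranking
    poorly predicted pathogenic mutations. Includes seeded synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    dplyr,
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
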