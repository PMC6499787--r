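Package: pulscape
Title: Composition, Synteny and Diversity Analysis of Polysaccharide
    Utilization Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to sort susC/D-anchored gene loci from Bacteroidetes
    gene tables into polysaccharide utilization loci (PULs), profile their
    CAZyme family composition, enumerate unique enzyme combinations, cluster
    compositions by Jaccard distance with average-linkage trees cut at
    mismatch thresholds, score gene-order (synteny) conservation with a
    normalized string-edit similarity, test family enrichment with
    chi-squared statistics and adjusted standardized residuals, and estimate
    saturation of enzyme-combination diversity by genome resampling with a
    quadratic trend. Includes a synthetic gene-table generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
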