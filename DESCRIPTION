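Package: orthoquant
Title: Cross-Species Expression Concordance via Ortholog Quantile Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing bulk or single-cell RNA-seq expression
    profiles between two species through an orthology-aware quantile
    mapping. Implements expression and high-expression gene calls from
    TPM matrices, decile binning of expressed genes, cross-tabulation of
    high-confidence ortholog pairs into an extended quantile-mapping
    matrix, Fisher exact enrichment of matrix regions, extraction and
    ranking of highly concordant orthologous genes, sample-similarity
    statistics (UPGMA clustering, PCA, ANOSIM and adonis permutation
    tests), EASE-score gene-set over-representation, and a synthetic
    paired-species data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
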