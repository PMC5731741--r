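Package: fgmd
Title: Functional Gene Module Detection from Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects overlapping functional gene modules from a genes-by-samples
    expression matrix using the FGMD seed-and-extend strategy: seed gene pairs
    are drawn from the top quantile of absolute Pearson correlations and
    filtered by degree, each pair is greedily expanded into a seed-pair
    expansion (SPE) module under a minimum-correlation rule, highly overlapping
    SPE modules are merged by hierarchical clustering on Jaccard dissimilarity
    with an adaptive dynamic tree cut, and each merged module is split back
    into tight final modules on correlation dissimilarity. Includes the
    associated module-validation battery (permutation test of in-module
    correlation coherence, hypergeometric gene-set enrichment with
    Benjamini-Hochberg correction, gene-list ratio statistics, weighted-network
    summary statistics), expression preprocessing utilities, a planted-block
    synthetic expression generator, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
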