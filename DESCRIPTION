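Package: funcpanel
Title: Functional Variant Panels for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and benchmarks genomic prediction panels assembled from
    functionally annotated sequence variants (GWAS tags, cis molecular QTL,
    allele-specific expression and binding QTL, chromatin accessibility QTL,
    coding variants) against generic SNP-chip panels. Provides a synthetic
    dairy-cattle population generator with block-wise linkage disequilibrium,
    fixed-effect phenotype adjustment to yield deviations, iterative
    conditional GWAS, cis-QTL scans and two-stage allele-specific tests,
    LD-block tagging with MAF-spectrum matched panel construction, a Gibbs
    sampler for the BayesC-pi whole-genome regression model, and k-fold
    cross-validated accuracy and improvement metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    MASS,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
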