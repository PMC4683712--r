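Package: efnet
Title: Feed-Efficiency Phenotypes and Liver Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes residual feed-efficiency traits (residual feed intake,
    residual body-weight gain and residual intake and gain) from feeding-trial
    records, selects extreme efficiency groups, and analyses liver RNA-seq
    expression with a weighted gene co-expression network workflow: CPM/FPKM
    normalisation and filtering, soft-threshold adjacency and topological
    overlap, module detection with eigengene-trait correlation and module
    membership filtering, differential connectivity (KDiff) between efficiency
    groups, and hypergeometric term enrichment with Benjamini-Hochberg FDR.
    Includes a synthetic-data generator that plants modules, trait links,
    group-specific connectivity and enriched terms with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
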