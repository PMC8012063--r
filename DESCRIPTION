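Package: xtenrich
Title: Expression-Weighted Cross-Tissue Enrichment with Empirical Resampling Nulls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Threshold-free gene-set enrichment for multi-tissue differential
    expression studies. Combines per-gene p-values with Fisher's statistic (and a
    fold-change analogue) against empirically resampled null distributions with an
    escalating draw schedule, computes expression-weighted cross-tissue gene
    statistics that reward direction-consistent regulation, measures co-expression
    network connectivity between gene sets via the signed topological overlap
    matrix, and provides downstream set-overlap, direction-concordance, weighted
    correlation and actuarial mortality-rate procedures. Ships a synthetic-data
    generator with planted effects so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'shared-stats.R'
    'simulate.R'
    'enrichment.R'
    'crosstissue.R'
    'network.R'
    'compare.R'
    'mortality.R'
    'pipeline.R'
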