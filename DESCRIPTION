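Package: kcliqueomics
Title: K-Clique Community Analysis of Multi-Omics Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates microbiome, volatilome and 1H NMR metabolome feature
    tables from nutritional intervention cohorts into Spearman-correlation
    threshold networks, and characterises them through overlapping k-clique
    communities detected by clique percolation. Provides per-omics
    preprocessing (median relative-abundance filtering, log transforms,
    regional probabilistic quotient normalisation, fixed-width spectral
    binning), a two-step NMR feature reduction (L1-penalised multinomial
    logistic selection followed by correlation-based hierarchical
    agglomeration with cophenetic pruning and median pooling), per-group
    network construction under fixed or significance-driven correlation
    thresholds, network topology summaries with power-law degree-distribution
    fits, cross-group community matching, a synthetic multi-omics cohort
    generator for validation, and an end-to-end pipeline with Cytoscape
    compatible exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
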