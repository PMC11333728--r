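Package: crossdx
Title: Cross-Disease Shared Key Gene Discovery and Drug Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a cross-disease transcriptomics
    pipeline for discovering shared key genes between two diseases from
    multiple independent case/control expression cohorts. Provides
    empirical-Bayes moderated-t differential expression with the average
    log2 fold-change statistic, within-disease and cross-disease DEG
    intersection, a local genetic-association (Pearson) statistic with a
    permutation test, protein-protein interaction hub selection by seven
    topological centrality measures (degree, betweenness, closeness,
    stress, radiality, maximal neighborhood component, bottleneck),
    bipartite regulator ranking, hypergeometric gene-set enrichment,
    methylation beta-values, docking-score (binding affinity) matrix drug
    prioritization, and rule-based drug-likeness / ADMET screening. A
    synthetic-data module generates inputs with the statistical structure
    the analysis assumes (hierarchical per-gene variances, planted shared
    and disease-specific effects with known cross-disease correlation,
    planted network hubs, gene sets and binding-affinity matrices) so the
    whole pipeline is testable without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    igraph
Config/testthat/edition: 3
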