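Package: ceburden
Title: Cryptic Exon Burden Scoring and Co-Expression Network Analysis of
    TDP-43 Proteinopathy Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies TDP-43 loss-of-function from qPCR measurements of
    cryptic exon (CE) expression, stratifies subjects into low, intermediate
    and high CE-burden molecular subtypes by unsupervised hierarchical
    clustering, and computes a cumulative rank-sum CE Burden Score.
    Normalizes multiplexed (TMT) proteomic abundance matrices by iterative
    median polish of ratios to internal reference channels, filters by
    missingness, removes outlier samples and regresses out nuisance
    covariates by bootstrap regression.  Builds signed weighted
    co-expression networks from biweight midcorrelations (soft-threshold
    adjacency, topological overlap, dynamic tree cut with a
    partitioning-around-medoids stage, module eigenproteins, kME), tests
    module-trait and module-subtype associations, and performs one-tailed
    Fisher's exact gene-set enrichment against GMT collections.  A
    knockdown-neuron arm averages technical replicates, imputes missing
    values from a downshifted normal distribution, runs per-protein t-tests
    and classifies cross-modal concordance of proteome changes against
    tissue CE-burden correlations.  All inputs can be simulated with
    planted ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
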