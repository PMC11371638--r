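Package: NetSuscept
Title: Network Susceptibility Models for Case-Control Brain Morphometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether case-control brain morphometric alterations follow
    normative connectome architecture. Implements the two canonical network
    susceptibility models -- hub vulnerability (spatial correlation between
    regional alteration and weighted network centrality) and disease epicenter
    mapping (correlation between each region's normative connectivity profile
    and the whole-brain alteration map) -- with spatial-autocorrelation
    preserving spin-permutation nulls for cortical maps and label shuffles for
    subcortical maps. Includes empirical-Bayes ComBat harmonization of
    multi-site morphometry, mass-univariate case-control difference maps with
    FDR control, individualized abnormality z-score maps with subject-level
    network scores and clinical association tests, disease-stage and
    cross-disorder comparisons with Zou confidence intervals for dependent
    correlations, and a fully parameterized synthetic multi-site cohort
    generator with planted epicenters and hub-coupled effects providing ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, StatisticalMethod, BatchEffect
RoxygenNote: 7.3.3
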