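Package: topnet
Title: Trend-of-Progression Analysis of State-Specific Gene-Gene Interaction Networks
Version: 0.1.0
Authors@R: person("topnet", "developers", email = "topnet@example.org", role = c("aut", "cre"))
Description: Builds condition-specific gene-gene interaction networks by
    intersecting expression-correlation edges (Pearson p-value threshold)
    with a protein-protein interaction scaffold, tracks per-gene degree and
    clustering coefficient along an ordered disease-state sequence, and
    selects genes whose network prominence grows toward the disease state
    (the trend-of-progression, ToP, rule). Includes differential-expression
    filters, randomization null models with permutation p-values, hit-rate
    evaluation against an annotated cancer-gene catalog, early-detection
    marker screening, functional-module reduction and hypergeometric
    enrichment, plus a synthetic multi-state cohort generator with planted
    correlated modules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
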