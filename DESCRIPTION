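Package: gemdiff
Title: Differential Flux Analysis of Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for condition-specific analysis of genome-scale metabolic
    models (GEMs): reading and writing COBRA-style JSON and SBML models,
    declarative construction of diet- or condition-constrained models, flux
    balance analysis (FBA), alpha-suboptimal flux variability analysis (FVA),
    artificial-centering hit-and-run flux sampling, parsimonious FBA, and
    maximal cofactor (NADH) production capacity. On top of the solver layer it
    implements differential-flux consensus calls across methods, reaction- and
    pathway-level two-sample Z-tests, normalized flux sensitivity coefficients,
    cross-model network-structure comparison (presence matrices, Hamming
    similarity, hierarchical clustering, cluster Jaccard overlap, subsystem
    coverage, metabolic-task feasibility, Fisher association), omics-side
    enrichment statistics (hypergeometric over-representation, weighted Jaccard
    pathway overlap with bootstrap, isotopomer fractional labeling,
    flux-measurement correlation), and seeded generators for synthetic toy
    models and omics tables with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
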