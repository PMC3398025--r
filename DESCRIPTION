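Package: pertnet
Title: Perturbed Subnetwork and Hub Network Analysis for Case-Control
    Expression Data on Protein-Interaction Networks
Version: 0.1.0
Authors@R:
    person("pertnet", "maintainers", email = "pertnet@example.org",
           role = c("aut", "cre"))
Description: Detects significantly perturbed subnetworks ("active modules")
    in a protein-protein interaction network from two-group expression data.
    Genes are scored by a beta-uniform mixture (BUM) decomposition of
    differential-expression p-values obtained from empirical-Bayes moderated
    t-statistics; maximal-scoring connected subnetworks are found by an exact
    enumerator (small graphs) or a minimum-spanning-tree heuristic; hub genes
    are extracted at a degree quantile and assembled into a cross-condition
    hub network whose perturbation, overlap, gene-set over-representation and
    severity-score correlation are quantified. Includes a synthetic-data
    module (scale-free interactome, planted differentially expressed module,
    BUM p-value draws, severity scores) so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
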