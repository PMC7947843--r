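Package: phylotriage
Title: Diagnosing and Resolving Phylogenomic Incongruence at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing and resolving incongruence among phylogenomic
    results from ultraconserved-element (UCE) style locus collections. Implements
    locus filtering by five per-locus statistics (average bootstrap, clocklikeness,
    GC proportion, parsimony-informative sites, saturation slope), entropy-based
    within-locus core/flank partitioning for gene-tree estimation, gene-based
    topology testing (gene genealogy interrogation with the approximately
    unbiased test over a multiscale RELL bootstrap), and quartet-based summary
    species-tree estimation with coalescent-unit branch lengths. A multispecies
    coalescent simulator generates UCE-like locus alignments with a conserved
    core, variable flanks, incomplete lineage sorting and per-locus missing
    taxa, so every stage of the pipeline can be exercised and validated without
    external data. Maximum-likelihood gene trees are estimated with a compiled
    pruning-likelihood engine supporting JC69/HKY85/GTR models, discrete-gamma
    rate variation, partitioned (edge-linked) models, constrained NNI searches,
    nonparametric bootstrap and per-site log-likelihoods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    phangorn,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
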