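Package: aptanet
Title: Similarity-Network Analysis of Riboswitch Aptamer Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the relative conservation of homologous
    structured-RNA elements with similarity networks instead of
    phylogenetic trees, developed around the glycine riboswitch.
    Classifies riboswitch architectures (tandem aptamer pairs, singleton
    types 1/2/0) and genomic contexts from hit coordinates; scores
    pairwise aptamer similarity by combining global-alignment sequence
    identity with a mountain-function structural distance on predicted
    secondary structures; builds thresholded similarity networks and
    quantifies conservation by intra- and inter-group edge density
    across threshold sweeps; extracts consensus communities shared by
    several detection algorithms; measures cluster stability by a
    parametric edge-perturbation bootstrap; and compares edge-weight
    distributions with the Wilcoxon rank-sum test.  A synthetic cohort
    generator emulating context-dependent tandem-to-singleton
    degradation provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
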