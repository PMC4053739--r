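Package: redens
Title: Clustering-Free Regulatory Element Discovery from Expression-Space Motif Densities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers IUPAC DNA motifs whose presence in gene-associated
    sequences depends statistically on the genes' expression profiles,
    without clustering the expression data. Motif densities are estimated
    locally around each gene with a hubness-corrected k-neighbor graph,
    candidate q-mer seeds are selected by an empirical shuffle false
    discovery rate, refined by constrained greedy generalization and
    elongation of the IUPAC consensus, and de-duplicated by sequence
    overlap and density-profile correlation. Per-gene density z-scores,
    positional histograms, strand-bias sign tests, expression heatmaps,
    cluster-based baseline scores and a PWM-database matching protocol
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    Rcpp,
    Biostrings,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
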