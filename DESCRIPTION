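Package: introgrescan
Title: Genome-Wide Introgression Scans for Admixed Species Radiations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects and characterises genetic introgression among closely
    related lineages from multi-sample SNP data. Implements genome-wide
    ABBA-BABA statistics (Patterson's D and the f4-ratio) with block-jackknife
    significance and Bonferroni trio filtering, window-based fdM scans with
    candidate-window selection and adjacency-enrichment statistics, net
    nucleotide divergence (D_A) split-time estimation with a chromosome-delete
    jackknife, and windowed neighbour-joining consensus trees with block
    bootstrap support. A structured-coalescent simulator generates genotype
    data with a known admixture pulse, linked introgressed tracts and planted
    QC failures for calibration and parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
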