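Package: kmerBeta
Title: Benchmarking k-mer Spectrum Beta-Diversity Against Taxonomic
    Ground Truth in Simulated Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for evaluating reference-free (k-mer
    based) comparative metagenomics. Generates mock communities with
    log-normal relative abundances from synthetic genome pools, simulates
    paired-end shotgun reads with platform-style substitution-error ramps
    and optional host/PhiX-like contamination, counts canonical k-mers,
    and computes Bray-Curtis and presence/absence Jaccard beta-diversity
    distances on exact spectra, on bottom-s MinHash sketches, and on
    abundance-filtered spectra. An evaluation harness quantifies the
    agreement between k-mer and ground-truth taxonomic distances via
    Spearman correlation, absolute-error summaries, Ward clustering
    purity, PERMANOVA and principal coordinates analysis, and a
    config-driven experiment runner reproduces the depth, technology,
    contamination, richness, taxonomic-diversity, sketching and filtering
    experiments at configurable scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    vegan,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
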