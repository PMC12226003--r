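Package: phnomp
Title: Phosphonate (phn) Gene-Cluster Screening and Oxic Methane Production Quantitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for two computational arms of studies on aerobic methane
    production from methylphosphonate (MPn) degradation. The survey arm
    screens prokaryotic genomes for intact C-P lyase (phn) gene clusters
    using profile-HMM hits filtered at per-model trusted cutoffs and a
    windowed co-localization rule (at least five distinct phn families
    within a 16 kb window on one contig, with the phnK/phnL/phnM core
    present), then rolls prevalence up by habitat and taxonomy. The
    incubation arm converts gas-chromatography headspace measurements to
    dissolved and total methane via a calibration curve and the Bunsen
    solubility coefficient, estimates volumetric production rates, computes
    methane-to-dissolved-organic-phosphorus consumption stoichiometry, and
    tests phosphate repression of methane production. A synthetic-data
    module plants gene clusters, decoys and incubation kinetics so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
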