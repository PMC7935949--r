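Package: ribostall
Title: Ribosome Stalling Analysis from Ribo-Seq, RNA-Seq and Polysome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting ribosome stalling from ribosome
    profiling data: P-site offset calibration by metagene analysis, triplet
    periodicity quality control, weighted exon-union counting of ribosome
    protected fragments (RPF) over CDS and mRNA reads over transcripts,
    TMM-log2 normalization, six-category translational-control
    classification, single-codon pause calling with replicate-consensus and
    genotype-exclusive logic, center-of-ribosome-density 5'/3' shift
    detection, and polysome-profile PS/MS run-off quantification. Includes a
    synthetic-data generator that plants known offsets, pauses, density
    skews and translational effects so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    Biostrings,
    rtracklayer,
    pracma,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
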