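Package: termfa
Title: Marker Frequency Analysis of Terminus Over-Replication in Bacterial Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify over-replication of the chromosomal terminus (Ter)
    region of Escherichia coli from marker frequency analysis (MFA) by deep
    sequencing, together with a generative simulator of bacterial replication
    profiles. Includes binning of mapped reads into genome windows, normalization
    against a stationary-phase control, circular loess smoothing, the
    spectinomycin Ter-peak-increase statistic, marker-locus and amplification
    copy-ratio estimators, 2^-dCt relative quantification for qPCR, and a
    stochastic model of R-loop-dependent replication with polar Ter/Tus fork
    trapping, chromosomal inversion and gene amplification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
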