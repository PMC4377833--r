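Package: msiamp
Title: Microsatellite Instability Calling from Amplicon Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Alignment-free microsatellite instability (MSI) testing from
    paired-end amplicon deep-sequencing reads. Overlapping mates are merged,
    quality-filtered, binned to marker loci by flanking-primer lookup, and
    summarised as per-locus amplicon length distributions. Locus instability
    is called from the deviation of the tumour modal amplicon length relative
    to a matched normal (or a fixed panel reference for quasimonomorphic
    markers), and locus calls are combined into an overall MSI-H/MSI-L/MSS
    status. Ships the five-marker colorectal panel (BAT25, BAT26, BAT34c4,
    D18S55, D5S346), evaluation utilities (confusion matrices with exact
    binomial confidence intervals), and a configurable paired-end read
    simulator with PCR stutter for end-to-end validation without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
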