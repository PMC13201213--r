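Package: pirnasig
Title: Oxidized Small-RNA piRNA Signature Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting PIWI-interacting RNA (piRNA)
    signatures in oxidized small RNA-seq libraries: adapter/UMI preprocessing,
    exhaustive k-mismatch read placement with all-best-strata reporting against
    infrastructural RNA, genome and transposon-consensus references, sense and
    antisense transposon signatures (size distributions, positional nucleotide
    frequencies, ping-pong 1U/10A z-scores, phased-biogenesis downstream-uridine
    frequency), masked genome-tile quantification of piRNA-cluster abundance,
    and length-normalized transposon mRNA abundance. A seeded simulator
    generates raw FASTQ libraries carrying the biogenesis structure the
    analysis detects (1U bias, ping-pong partners, phased 3' ends,
    2'-O-methylation and periodate oxidation, hairpin-RNA siRNA, microRNA and
    degradation backgrounds) together with a ground-truth table, so every stage
    is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
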