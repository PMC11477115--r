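Package: cubtools
Title: Codon Usage Bias Analysis for Organellar Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete codon-usage-bias (CUB) workbench for chloroplast (and
    other organellar) coding sequences: CDS extraction from GenBank or FASTA
    with start/stop/frame/length filtering, nucleotide composition and the six
    pairwise skews, the full index suite (RSCU, RFSC, Wright's effective number
    of codons with its expected GC3s curve, CAI, CBI, Fop, SCUO, MILC, GRAVY,
    aromaticity, isoelectric point), high-frequency and optimal codon
    classification from ENC-defined expression deciles, mutation-versus-
    selection diagnostics (neutrality regression, ENC-plot, PR2-plot,
    correspondence analysis of RSCU, correlation suites), heterologous-host
    codon-frequency comparison, and RSCU-based hierarchical clustering of
    species. A seeded synthetic CDS generator with controllable GC3 and
    selection strength makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
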