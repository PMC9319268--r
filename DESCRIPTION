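Package: agaritype
Title: Diagnostic-Position ITS Genotyping for the Agaricus subrufescens
    Species Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for typing internal transcribed spacer (ITS) haplotypes in
    Agaricus sect. Arvenses from characteristic polymorphisms at 14 diagnostic
    alignment positions. Classifies homo- and heterokaryotic samples into ITS
    type calls (A, B, C, M and their combinations), decomposes IUPAC-coded
    heterokaryon consensus sequences into component haplotypes, deconvolves
    Sanger electropherogram traces superposed with an offset by a length
    polymorphism, discovers species-specific marker columns in grouped
    alignments with flank notation, and builds UPGMA trees over diagnostic
    state distances. Includes a packaged 66-sample reference state matrix and
    a seeded synthetic-data generator so the whole pipeline is testable
    without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
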