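Package: topogel
Title: Plasmid Supercoiling Density from Two-Dimensional Topoisomer Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies in-vivo plasmid supercoiling density from one- and
    two-dimensional chloroquine agarose gel topoisomer ladders using the
    band-counting method with intercalator and temperature corrections.
    Includes a virtual-gel simulator for validating the pipeline by
    parameter recovery, band detection and writhe assignment for 1D
    intensity profiles, a synthetic three-strain transcriptome generator
    with supercoiling-responsive gene calling by triple contrast, IUPAC
    consensus motif scanning, and growth-rate and plasmid-retention
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
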