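Package: barcodeval
Title: Evaluation of DNA Barcoding Identification and Species Discovery Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate DNA barcode reference libraries: Kimura (1980)
    pairwise distances with pairwise deletion of missing and ambiguous sites,
    nearest-neighbour, best-close-match and threshold specimen identification
    with cumulative-error threshold optimization, tree-based ("liberal")
    identification on support-collapsed phylogenies, barcode-gap and Poisson
    tree processes species discovery, and congruence scoring of genetic
    entities against named species. Includes a synthetic reference-library
    simulator (multi-genus, multi-marker, K80 sequence evolution) so that the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    seqinr,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
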