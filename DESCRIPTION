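Package: cd28family
Title: Classification of Vertebrate CD28/CTLA4-Family Receptors from Motif,
    Architecture and Synteny Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assign vertebrate receptor protein sequences to the
    nine-member CD28/CTLA4 family (CD28, CTLA4, ICOS, CD28H, CD28HL1-3,
    CD28X and PD-1). Combines three evidence layers: scanning of degenerate
    consensus motifs written in the compact notation used in comparative
    immunogenetics, validation of the single-IgV/transmembrane/cytoplasmic
    type-I membrane architecture, and conserved-synteny marker scoring on
    gene-order tables, including detection of the ancestral three-gene
    cd28/ctla4/icos cassette and counting of paralogous regions retained
    after whole-genome duplications. A neighbor-joining layer with bootstrap
    support and a fully parameterised synthetic-data generator (proteins
    with planted domains and motifs; genomes with marker blocks, WGD and
    gene loss) make every stage testable without genome downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
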