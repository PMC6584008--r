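Package: BarcodeMatch
Title: Adjudication of DNA Barcode Database Search Hits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for scoring taxonomic identifications obtained by
    searching DNA barcode sequences (COI, rbcL, matK, trnH-psbA, ITS)
    against the BOLD identification engine and GenBank BLAST. Reads
    BLAST tabular (outfmt 6) output, BOLD identification-engine exports
    and archived spreadsheet workbooks into a canonical hit-table model,
    computes the set of records sharing the best match statistics per
    query (tie detection on e-value, bit score, percent identity or BOLD
    similarity), classifies each identification as a reliable correct
    match, ambiguous correct match, misidentification or no match
    against known specimen taxonomy, rolls assignments up the taxonomic
    hierarchy, combines per-locus results into multi-locus
    identifications, and summarises accuracy and ambiguity by database,
    taxonomic group and rank with supporting t-tests and one-way ANOVA.
    A seeded simulator generates reference databases and hit tables with
    controlled rates of tied top statistics, mislabelled, undetermined
    and uncultured records so the whole pipeline is testable without
    live database queries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    yaml,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Classification, SequenceMatching, Software
RoxygenNote: 7.3.3
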