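Package: clonetrack
Title: Contemporaneous Sample Tracking for Genome-Edited Cell Line Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-sourced activity ledger and sample-provenance registry for
    the generation of clonal genome-edited cell lines. Samples are named by a
    grammar that encodes transfection date, fluorescent-protein, target-gene and
    guide-RNA tokens plus well and sort-number suffixes; the registry derives a
    lineage forest from the ledger and mirrors it as nested directories that act
    as local persistent identifiers. Data entry is restricted by controlled
    vocabularies, and recomputable reports (per-activity, per-transfection,
    passage counts, clone summaries) export losslessly to CSV, XML and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readr,
    tibble,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
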