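Package: seedtrace
Title: Traceability of Seed Lots in Decentralised Breeding Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A traceability engine for seed lots exchanged and multiplied in
    participatory plant breeding networks. Seed lots (a named quantity of seeds
    of one germplasm, at one location, in one year) are linked by typed events
    (reproduction, cross, selection, mixture, diffusion) forming a directed
    acyclic provenance graph. The package provides gram-based stock accounting
    with inventory resets, six tabulated import/export file formats with
    two-phase atomic validation, pedigree and generation-number queries,
    alone/cascade deletion of event subtrees, a deterministic synthetic network
    generator for testing, and a command-line interface over a single-file
    store.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
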