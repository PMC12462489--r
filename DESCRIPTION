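Package: sdrfkit
Title: Create, Validate and Apply SDRF-Proteomics Metadata for Quantitative Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with SDRF-Proteomics (Sample and Data
    Relationship Format) metadata in mass-spectrometry proteomics. Builds a
    compact one-row-per-sample metadata table from an experimental design
    (expanding multiplexed label channels and collapsing fractionated raw
    files), writes standards-compliant SDRF files with ontology-annotated
    data-file properties from offline controlled-vocabulary lookups, reads
    and validates SDRF files, annotates quantitative protein-group tables
    with per-column sample properties, and exports expression matrix plus
    sample-annotation pairs ready for differential-expression tools.
    Includes seeded generators for synthetic designs and protein-group
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    yaml,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
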