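Package: ferretforge
Title: Construction and Validation of Marine Eukaryote Reference Protein Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building quality-controlled reference protein
    libraries from heterogeneous genome and transcriptome sequence entries,
    oriented towards marine microbial eukaryote metatranscriptome annotation.
    Provides six-frame translation with longest-ORF frame selection,
    trusted-cutoff filtering and best-per-sequence reduction of Pfam domain
    annotations, lowest-common-ancestor taxonomic placement of ribosomal
    protein markers for cross-contamination estimation, threshold-based entry
    validation flags, within-taxon protein identity clustering with stable
    identifier assignment, and derivation of core transcribed gene catalogs
    with completeness scoring. Deterministic synthetic-fixture generators
    emulate every input format so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
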