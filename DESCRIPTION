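Package: pacsdwh
Title: Pseudonymized Extraction of DICOM Metadata and Images from a PACS
    into a Research Data Warehouse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to integrate a hospital picture archiving and
    communication system (PACS) with a pseudonymized clinical research
    data warehouse. Provides a query/retrieve client with find and
    download semantics (time ranges, patient identifiers, instance UIDs,
    accession numbers, modalities), DICOM header de-identification with a
    modality block-list, transient identity mapping between PACS
    identifiers and research pseudonyms, an extended entity-attribute-value
    store that links image-level metadata groups to radiology report
    documents via the accession number, three bulk metadata extraction
    strategies with per-patient performance accounting and whole-hospital
    extrapolation, a session-scoped ad hoc query service with audit
    logging and JPEG/DICOM image export, and a reproducible synthetic
    DICOM cohort generator that stands in for a production PACS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    digest,
    DBI,
    RSQLite,
    jpeg,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
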