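Package: oculink
Title: Deterministic Linkage of Ophthalmic DICOM Archives to EHR Registry Rosters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated pipeline for linking ophthalmic imaging archives to
    an electronic health record registry at the patient level. Extracts and
    flattens the first two levels of DICOM metadata, harmonizes patient
    identifiers on both the imaging and registry sides, applies data-quality
    exclusion rules (numeric or special-character names, abnormal birthdates,
    test patients), links patients through four deterministic
    identifier-combination rules with practice-location blocking and
    graph-based one-to-one matching, propagates links to images and
    encapsulated key-measurement documents, masks protected health
    information while preserving DICOM tag structure, tokenizes patient
    identifiers with a keyed digest, and reports cohort-diagram counts and
    linkage rates stratified by last-visit year and image type. Ships a
    synthetic multi-practice cohort generator with ground truth so every
    stage can be evaluated (precision, recall) without access to real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    openssl,
    stats,
    tools,
    utils,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
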