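Package: consentcodes
Title: Consent Codes for Governing Re-Use of Shared Data and Biospecimens
Version: 0.4.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An executable implementation of the Consent Codes (v4) vocabulary
    for consent-based data and biospecimen use conditions in open science.
    Parses and validates consent-code profiles attached to datasets and
    biobank collections, decides whether a structured research-use request is
    permitted under a profile (with obligations, granted permissions and an
    explainable rule trace), filters dataset catalogs by permitted use, and
    crosswalks codes to GA4GH Data Use Ontology (DUO) terms and HL7 research
    Purpose-of-Use codes with fidelity and caution annotations. Ships seeded
    synthetic generators and an independent brute-force oracle for exhaustive
    property-based testing of the decision engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
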