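Package: oncoharmonizer
Title: Dictionary-Driven Harmonization, Quality Scoring, and FHIR R4B Export
    of Oncology Clinical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An extract-transform-load toolkit for multicentre oncology
    studies that capture patient-level clinical data through REDCap-style
    forms. A machine-readable data dictionary binds each study variable to a
    datatype, a requirement tier (minimal/mandatory/recommended), a value set
    with ontology codes (SNOMED CT, ICD-O-3, LOINC, RxNorm, NCIT, HL7/FHIR),
    and a target FHIR R4B resource element. The package parses REDCap raw-code
    CSV exports, runs a weighted three-dimension quality assessment
    (completeness, conformance, plausibility) with a scored report, applies
    pseudonymization transforms (double-hashed patient identifiers,
    interval-to-epoch date recoding), emits one FHIR R4B JSON bundle per
    patient, and validates the emitted bundles with an independent structural
    validator. A seeded synthetic-cohort generator with bookkept fault
    injection makes every stage testable without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
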