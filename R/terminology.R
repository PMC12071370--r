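# Terminology registry and ontology codings.
#
# The registry is closed: value sets may only bind codes from the six
# terminology families used across the data schemas. SNOMED CT is the
# preferred system for general clinical concepts, ICD-O-3 covers tumour
# histology/topography, LOINC test observations, RxNorm medications, and
# NCIT fills concepts absent from the others; HL7/FHIR code systems are
# reserved for status-like elements fixed by the FHIR specification.

SYSTEM_SNOMED <- "http://snomed.info/sct"
SYSTEM_LOINC <- "http://loinc.org"
SYSTEM_RXNORM <- "http://www.nlm.nih.gov/research/umls/rxnorm"
SYSTEM_NCIT <- "http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl"
SYSTEM_ICDO3 <- "http://terminology.hl7.org/CodeSystem/icd-o-3"
HL7_PREFIXES <- c(
  "http://hl7.org/fhir/",
  "http://terminology.hl7.org/CodeSystem/"
)

#' Registered terminology systems
#'
#' The closed registry of code-system URIs a dictionary may bind. HL7/FHIR
#' systems are matched by prefix (the family spans many small code systems,
#' e.g. administrative-gender and data-absent-reason).
#'
#' @return named character vector of canonical system URIs.
#' @export
terminology_systems <- function() {
  c(
    snomed = SYSTEM_SNOMED,
    loinc = SYSTEM_LOINC,
    rxnorm = SYSTEM_RXNORM,
    ncit = SYSTEM_NCIT,
    icdo3 = SYSTEM_ICDO3,
    hl7 = "http://terminology.hl7.org/CodeSystem/"
  )
}

#' Terminology release versions carried as metadata
#'
#' Release identifiers of the terminology versions the value sets were
#' authored against. Recorded for provenance only; no live terminology
#' service is consulted and codes are never validated against a release.
#'
#' @return named character vector of version strings.
#' @export
terminology_versions <- function() {
  c(
    snomed = "International 2022-12-31",
    icdo3 = "20220429",
    loinc = "2.73",
    rxnorm = "2023-01-03",
    ncit = "23.8d"
  )
}

is_registered_system <- function(system) {
  if (!is_string(system)) return(FALSE)
  system %in% c(SYSTEM_SNOMED, SYSTEM_LOINC, SYSTEM_RXNORM, SYSTEM_NCIT,
                SYSTEM_ICDO3) ||
    any(startsWith(system, HL7_PREFIXES))
}

# SNOMED compositional-grammar expressions contain refinement syntax
# (":", "=", "+", "|...|"). They are carried as opaque strings.
is_postcoordinated <- function(code) {
  grepl("[:=+|]", code)
}

#' Construct an ontology coding
#'
#' A (system, code, display) triple binding a concept to one of the six
#' registered terminology families. Post-coordinated expressions (SNOMED
#' compositional grammar) are permitted only under the SNOMED CT system and
#' are treated as opaque strings.
#'
#' @param system code-system URI from the closed registry
#'   (see [terminology_systems()]).
#' @param code non-empty code string.
#' @param display optional human-readable label.
#' @return an object of class `oh_coding`.
#' @export
#' @examples
#' coding("http://snomed.info/sct", "254837009", "Malignant tumor of breast")
coding <- function(system, code, display = NULL) {
  if (!is_registered_system(system)) {
    stop_oh(sprintf("unregistered terminology system: %s",
                    if (is_string(system)) system else "<non-string>"),
            "oh_terminology_error")
  }
  if (!is_string(code) || !nzchar(code)) {
    stop_oh("coding code must be a non-empty string", "oh_terminology_error")
  }
  if (is_postcoordinated(code) && !identical(system, SYSTEM_SNOMED)) {
    stop_oh(sprintf(
      "post-coordinated expressions are only permitted under SNOMED CT: %s",
      code), "oh_terminology_error")
  }
  structure(
    list(system = system, code = code, display = display),
    class = "oh_coding"
  )
}

#' @export
format.oh_coding <- function(x, ...) {
  sprintf("[%s] %s%s", x$system, x$code,
          if (!is.null(x$display)) paste0(" (", x$display, ")") else "")
}

#' @export
print.oh_coding <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

same_coding <- function(a, b) {
  identical(a$system, b$system) && identical(a$code, b$code)
}
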