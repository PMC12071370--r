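# Structural subset of the FHIR R4B schema used by the dictionary and the
# resource builders. Only the six resource kinds used by the data schemas are
# modelled, and for each kind only the element paths a dictionary may target.
# This is a pragmatic subset for build-time checking, not full profile
# conformance; the independent validator in fhir-validate.R keeps its own
# tables so it can act as an oracle over the builder's output.

RESOURCE_KINDS <- c("Patient", "Condition", "Observation", "Procedure",
                    "MedicationAdministration", "DiagnosticReport")

# Element paths addressable from a dictionary, with the FHIR datatype each
# populates and the dictionary datatypes allowed to feed it.
fhir_element_registry <- function() {
  reg <- list(
    list("Patient", "identifier", "Identifier", "string"),
    list("Patient", "gender", "code", "code"),
    list("Condition", "code", "CodeableConcept", "code"),
    list("Condition", "bodySite", "CodeableConcept", "code"),
    list("Condition", "onsetAge", "Age", c("integer", "decimal")),
    list("Condition", "onsetPeriod", "Period", "interval"),
    list("Observation", "valueCodeableConcept", "CodeableConcept", "code"),
    list("Observation", "valueQuantity", "Quantity", c("integer", "decimal")),
    list("Observation", "valueInteger", "integer", "integer"),
    list("Observation", "valueString", "string", "string"),
    list("Observation", "valueBoolean", "boolean", "boolean"),
    list("Observation", "effectivePeriod", "Period", "interval"),
    list("Procedure", "code", "CodeableConcept", "code"),
    list("Procedure", "performedPeriod", "Period", "interval"),
    list("MedicationAdministration", "medicationCodeableConcept",
         "CodeableConcept", "code"),
    list("MedicationAdministration", "dosage.dose", "Quantity",
         c("integer", "decimal")),
    list("MedicationAdministration", "extension.totalCycles", "integer",
         "integer"),
    list("MedicationAdministration", "extension.cumulativeDose", "Quantity",
         c("integer", "decimal")),
    list("MedicationAdministration", "effectivePeriod", "Period", "interval"),
    list("DiagnosticReport", "conclusionCode", "CodeableConcept", "code"),
    list("DiagnosticReport", "conclusion", "string", "string"),
    list("DiagnosticReport", "effectivePeriod", "Period", "interval")
  )
  data.frame(
    kind = vapply(reg, `[[`, "", 1L),
    element = vapply(reg, `[[`, "", 2L),
    fhir_type = vapply(reg, `[[`, "", 3L),
    datatypes = I(lapply(reg, `[[`, 4L)),
    stringsAsFactors = FALSE
  )
}

# Paths that may carry a fixed coding from the dictionary (per-resource
# metadata such as what an Observation measures, or status-like elements).
FIXED_CODING_PATHS <- c(
  "Observation.code", "DiagnosticReport.code", "Condition.category",
  "Observation.category", "Condition.clinicalStatus",
  "Condition.verificationStatus"
)

# Fixed HL7/FHIR status codes stamped onto every built resource of a kind.
builder_status_defaults <- function() {
  list(
    Observation = list(element = "status", code = "final"),
    Procedure = list(element = "status", code = "completed"),
    MedicationAdministration = list(element = "status", code = "completed"),
    DiagnosticReport = list(element = "status", code = "final")
  )
}

# Condition carries CodeableConcept statuses rather than a code primitive.
builder_condition_status <- function() {
  list(
    clinicalStatus = list(
      system = "http://terminology.hl7.org/CodeSystem/condition-clinical",
      code = "active", display = "Active"),
    verificationStatus = list(
      system = "http://terminology.hl7.org/CodeSystem/condition-ver-status",
      code = "confirmed", display = "Confirmed")
  )
}

DATA_ABSENT_SYSTEM <- "http://terminology.hl7.org/CodeSystem/data-absent-reason"
ADMIN_GENDER_CODES <- c("male", "female", "other", "unknown")

# Extension URIs for dosing facts the MedicationAdministration resource
# cannot hold natively (it is designed for a single administration entry,
# not a summarised regimen).
EXT_TOTAL_CYCLES <- "urn:oncoharmonizer:extension:total-cycles"
EXT_CUMULATIVE_DOSE <- "urn:oncoharmonizer:extension:cumulative-dose"

element_registry_lookup <- function(kind, element) {
  reg <- fhir_element_registry()
  hit <- reg[reg$kind == kind & reg$element == element, ]
  if (nrow(hit) == 0L) NULL else hit
}

#' Check an element path against the implemented R4B structural subset
#'
#' @param resource_kind one of the six supported resource kinds.
#' @param element_path dot-separated path, including the resource-kind
#'   prefix (e.g. `"Observation.valueQuantity"`).
#' @param datatype optional dictionary datatype; when given, also checks the
#'   path accepts it.
#' @return TRUE if valid, otherwise a character string describing the problem.
#' @export
check_element_path <- function(resource_kind, element_path, datatype = NULL) {
  if (!resource_kind %in% RESOURCE_KINDS) {
    return(sprintf("unknown resource kind '%s'", resource_kind))
  }
  prefix <- paste0(resource_kind, ".")
  if (!startsWith(element_path, prefix)) {
    return(sprintf("element path '%s' does not address resource kind '%s'",
                   element_path, resource_kind))
  }
  element <- substring(element_path, nchar(prefix) + 1L)
  hit <- element_registry_lookup(resource_kind, element)
  if (is.null(hit)) {
    return(sprintf("element path '%s' is not a supported %s element",
                   element_path, resource_kind))
  }
  if (!is.null(datatype) && !datatype %in% hit$datatypes[[1L]]) {
    return(sprintf(
      "element path '%s' (%s) does not accept dictionary datatype '%s'",
      element_path, hit$fhir_type, datatype))
  }
  TRUE
}
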