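# Independent structural + terminology validator for emitted bundles.
#
# Deliberately shares no tables or code paths with the resource builders:
# the structural knowledge below (allowed resource types, required elements,
# status code sets, primitive shapes) is declared afresh so the validator
# can act as an oracle over the builder's output. Terminology validation is
# membership-in-dictionary only — the codes a bundle may carry are exactly
# those the schema's value sets and fixed codings declare, plus the fixed
# HL7 status/housekeeping codes; no terminology server is consulted.

VAL_RESOURCE_TYPES <- c("Patient", "Condition", "Observation", "Procedure",
                        "MedicationAdministration", "DiagnosticReport")

# Required top-level elements per resource type (our archival profile).
VAL_REQUIRED <- list(
  Patient = c("identifier"),
  Condition = c("code", "subject", "clinicalStatus"),
  Observation = c("status", "code", "subject"),
  Procedure = c("status", "code", "subject"),
  MedicationAdministration = c("status", "medicationCodeableConcept",
                               "subject"),
  DiagnosticReport = c("status", "code", "subject")
)

# Fixed HL7 status value sets.
VAL_STATUS_SETS <- list(
  Observation = list(element = "status",
                     codes = c("registered", "preliminary", "final",
                               "amended", "corrected", "cancelled",
                               "entered-in-error", "unknown")),
  Procedure = list(element = "status",
                   codes = c("preparation", "in-progress", "not-done",
                             "on-hold", "stopped", "completed",
                             "entered-in-error", "unknown")),
  MedicationAdministration = list(element = "status",
                                  codes = c("in-progress", "not-done",
                                            "on-hold", "completed",
                                            "entered-in-error", "stopped",
                                            "unknown")),
  DiagnosticReport = list(element = "status",
                          codes = c("registered", "partial", "preliminary",
                                    "final", "amended", "corrected",
                                    "appended", "cancelled",
                                    "entered-in-error", "unknown"))
)

VAL_GENDER_CODES <- c("male", "female", "other", "unknown")
VAL_URN_RE <- "^urn:uuid:[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$"
VAL_DATE_RE <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}$"

# Codes every bundle may carry regardless of schema: condition statuses,
# the data-absent-reason fallback.
val_builtin_codings <- function() {
  list(
    list(system = "http://terminology.hl7.org/CodeSystem/condition-clinical",
         codes = c("active", "recurrence", "relapse", "inactive",
                   "remission", "resolved")),
    list(system = "http://terminology.hl7.org/CodeSystem/condition-ver-status",
         codes = c("unconfirmed", "provisional", "differential", "confirmed",
                   "refuted", "entered-in-error")),
    list(system = "http://terminology.hl7.org/CodeSystem/data-absent-reason",
         codes = c("unknown", "asked-unknown", "temp-unknown", "not-asked",
                   "asked-declined", "masked", "not-applicable",
                   "unsupported", "as-text", "error", "not-a-number",
                   "negative-infinity", "positive-infinity", "not-performed",
                   "not-permitted", "not-provided"))
  )
}

# The terminology universe a schema admits: value-set codings + fixed
# codings, as (system, code) pairs.
schema_coding_universe <- function(schema) {
  pairs <- list()
  for (v in schema$variables) {
    for (e in v$value_set) {
      pairs[[length(pairs) + 1L]] <- c(e$coding$system, e$coding$code)
    }
    for (fc in v$fixed_codings) {
      pairs[[length(pairs) + 1L]] <- c(fc$system, fc$code)
    }
  }
  for (b in val_builtin_codings()) {
    for (code in b$codes) pairs[[length(pairs) + 1L]] <- c(b$system, code)
  }
  unique(vapply(pairs, paste, "", collapse = "\r"))
}

new_finding <- function(file, path, severity, rule, message) {
  data.frame(file = file, path = path, severity = severity, rule = rule,
             message = message, stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(file = character(), path = character(), severity = character(),
             rule = character(), message = character(),
             stringsAsFactors = FALSE)
}

# Recursively visit every "coding" array and check membership in the
# terminology universe; also check coding shape (system + code present).
check_codings <- function(node, path, universe, file) {
  findings <- no_findings()
  if (!is.list(node)) return(findings)
  nms <- names(node)
  for (i in seq_along(node)) {
    child <- node[[i]]
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else
      sprintf("[%d]", i)
    cpath <- paste(path, nm, sep = ".")
    if (identical(nm, "coding") && is.list(child)) {
      for (j in seq_along(child)) {
        cd <- child[[j]]
        cdpath <- sprintf("%s[%d]", cpath, j)
        if (is.null(cd$system) || is.null(cd$code)) {
          findings <- rbind(findings, new_finding(
            file, cdpath, "error", "coding-shape",
            "coding lacks system or code"))
        } else if (!paste(cd$system, cd$code,
                          sep = "\r") %in% universe) {
          findings <- rbind(findings, new_finding(
            file, cdpath, "error", "terminology",
            sprintf("code '%s' (%s) is not bound by the dictionary",
                    cd$code, cd$system)))
        }
      }
    } else if (is.list(child)) {
      findings <- rbind(findings, check_codings(child, cpath, universe,
                                                file))
    }
  }
  findings
}

check_period <- function(node, path, file) {
  findings <- no_findings()
  bad_date <- function(x) !is_string(x) || !grepl(VAL_DATE_RE, x)
  if (is.null(node$start) || bad_date(node$start)) {
    findings <- rbind(findings, new_finding(
      file, paste0(path, ".start"), "error", "datatype",
      "period start is not a calendar date (YYYY-MM-DD)"))
  }
  if (is.null(node$end) || bad_date(node$end)) {
    findings <- rbind(findings, new_finding(
      file, paste0(path, ".end"), "error", "datatype",
      "period end is not a calendar date (YYYY-MM-DD)"))
  }
  if (nrow(findings) == 0L &&
      as.Date(node$end) < as.Date(node$start)) {
    findings <- rbind(findings, new_finding(
      file, path, "error", "datatype", "period ends before it starts"))
  }
  findings
}

check_resource <- function(res, path, universe, patient_urn, file) {
  findings <- no_findings()
  rt <- res$resourceType
  if (is.null(rt) || !rt %in% VAL_RESOURCE_TYPES) {
    return(new_finding(file, paste0(path, ".resourceType"), "error",
                       "resource-type",
                       sprintf("illegal resourceType '%s'",
                               rt %||% "<absent>")))
  }
  for (req in VAL_REQUIRED[[rt]]) {
    if (is.null(res[[req]])) {
      findings <- rbind(findings, new_finding(
        file, paste(path, req, sep = "."), "error", "required-element",
        sprintf("%s requires element '%s'", rt, req)))
    }
  }
  ss <- VAL_STATUS_SETS[[rt]]
  if (!is.null(ss) && !is.null(res[[ss$element]]) &&
      !res[[ss$element]] %in% ss$codes) {
    findings <- rbind(findings, new_finding(
      file, paste(path, ss$element, sep = "."), "error", "status-code",
      sprintf("'%s' is not a legal %s %s code", res[[ss$element]], rt,
              ss$element)))
  }
  if (rt == "Patient" && !is.null(res$gender) &&
      !res$gender %in% VAL_GENDER_CODES) {
    findings <- rbind(findings, new_finding(
      file, paste0(path, ".gender"), "error", "status-code",
      sprintf("'%s' is not an administrative-gender code", res$gender)))
  }
  if (rt != "Patient") {
    ref <- res$subject$reference
    if (!is.null(res$subject) &&
        (!is_string(ref) || !identical(ref, patient_urn))) {
      findings <- rbind(findings, new_finding(
        file, paste0(path, ".subject.reference"), "error", "reference",
        sprintf("subject reference '%s' does not resolve to the bundle's Patient",
                ref %||% "<absent>")))
    }
  }
  # datatype spot checks on the elements this profile uses
  for (nm in names(res)) {
    el <- res[[nm]]
    epath <- paste(path, nm, sep = ".")
    if (nm %in% c("effectivePeriod", "performedPeriod", "onsetPeriod")) {
      findings <- rbind(findings, check_period(el, epath, file))
    }
    if (nm %in% c("valueQuantity", "onsetAge")) {
      if (is.null(el$value) || !is.numeric(el$value)) {
        findings <- rbind(findings, new_finding(
          file, paste0(epath, ".value"), "error", "datatype",
          "quantity value is absent or non-numeric"))
      }
    }
    if (nm == "valueInteger" &&
        (!is.numeric(el) || length(el) != 1L || el != floor(el))) {
      findings <- rbind(findings, new_finding(
        file, epath, "error", "datatype", "valueInteger is not an integer"))
    }
    if (nm == "effectiveDateTime" &&
        (!is_string(el) || !grepl(VAL_DATE_RE, el))) {
      findings <- rbind(findings, new_finding(
        file, epath, "error", "datatype",
        "effectiveDateTime is not a calendar date"))
    }
  }
  rbind(findings, check_codings(res, path, universe, file))
}

#' Validate one bundle against the structural subset and the dictionary
#'
#' Checks: resource-type legality, required elements, datatype conformance,
#' reference closure, fixed HL7 status codes, terminology membership in the
#' dictionary's value sets, URN shape and uniqueness, Patient-first and
#' single-Patient bundle structure. An empty findings frame means valid.
#'
#' @param x a bundle file path, or an `oh_bundle`/parsed bundle list.
#' @param schema the governing `oh_schema`.
#' @return data.frame of findings (file, path, severity, rule, message).
#' @export
validate_bundle <- function(x, schema) {
  stopifnot(inherits(schema, "oh_schema"))
  file <- "<in-memory>"
  if (is.character(x)) {
    file <- basename(x)
    doc <- tryCatch(jsonlite::fromJSON(x, simplifyVector = FALSE),
                    error = function(e) e)
    if (inherits(doc, "error")) {
      return(new_finding(file, "$", "error", "parse",
                         sprintf("unparseable JSON: %s",
                                 conditionMessage(doc))))
    }
    x <- doc
  }
  x <- unclass(x)
  findings <- no_findings()
  if (!identical(x$resourceType, "Bundle")) {
    return(new_finding(file, "$.resourceType", "error", "bundle-structure",
                       "document is not a FHIR Bundle"))
  }
  if (!identical(x$type, "collection")) {
    findings <- rbind(findings, new_finding(
      file, "$.type", "error", "bundle-structure",
      sprintf("bundle type '%s' is not 'collection'", x$type %||%
                "<absent>")))
  }
  entries <- x$entry %||% list()
  if (length(entries) == 0L) {
    return(rbind(findings, new_finding(
      file, "$.entry", "error", "bundle-structure", "bundle has no entries")))
  }
  urns <- vapply(entries, function(e) e$fullUrl %||% "", "")
  for (i in seq_along(urns)) {
    if (!grepl(VAL_URN_RE, urns[i])) {
      findings <- rbind(findings, new_finding(
        file, sprintf("$.entry[%d].fullUrl", i), "error", "urn",
        sprintf("'%s' is not a urn:uuid URN", urns[i])))
    }
  }
  if (anyDuplicated(urns)) {
    findings <- rbind(findings, new_finding(
      file, "$.entry", "error", "urn", "entry URNs are not distinct"))
  }
  types <- vapply(entries, function(e)
    e$resource$resourceType %||% "<absent>", "")
  patient_idx <- which(types == "Patient")
  if (length(patient_idx) != 1L) {
    findings <- rbind(findings, new_finding(
      file, "$.entry", "error", "bundle-structure",
      sprintf("bundle must hold exactly one Patient (found %d)",
              length(patient_idx))))
  } else if (patient_idx != 1L) {
    findings <- rbind(findings, new_finding(
      file, "$.entry", "error", "bundle-structure",
      "Patient is not the first entry"))
  }
  patient_urn <- if (length(patient_idx) >= 1L) urns[patient_idx[1L]] else ""
  universe <- schema_coding_universe(schema)
  for (i in seq_along(entries)) {
    findings <- rbind(findings, check_resource(
      entries[[i]]$resource %||% list(), sprintf("$.entry[%d].resource", i),
      universe, patient_urn, file))
  }
  findings
}

#' Validate a directory of bundle files
#'
#' @param dir directory holding `.json` bundle files.
#' @param schema the governing `oh_schema`.
#' @return object of class `oh_validation_summary`: files checked, valid
#'   count, findings frame (a warning-level finding for an empty directory).
#' @export
validate_cohort <- function(dir, schema) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  findings <- no_findings()
  valid <- 0L
  if (length(files) == 0L) {
    findings <- new_finding("<directory>", dir, "warning", "empty-input",
                            "no bundle files found")
  }
  for (f in files) {
    fnd <- validate_bundle(f, schema)
    if (!any(fnd$severity == "error")) valid <- valid + 1L
    findings <- rbind(findings, fnd)
  }
  structure(
    list(files = length(files), valid = valid, findings = findings),
    class = "oh_validation_summary"
  )
}

#' @export
print.oh_validation_summary <- function(x, ...) {
  cat(sprintf("%d/%d bundles valid\n", x$valid, x$files))
  err <- x$findings[x$findings$severity == "error", ]
  if (nrow(err) > 0L) {
    for (i in seq_len(nrow(err))) {
      cat(sprintf("  %s %s [%s] %s\n", err$file[i], err$path[i],
                  err$rule[i], err$message[i]))
    }
  }
  invisible(x)
}
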