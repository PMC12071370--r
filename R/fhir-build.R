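# Dictionary-driven FHIR R4B bundle construction: one bundle per patient
# record, resources addressed by urn:uuid URNs, Patient first, every clinical
# resource referencing the Patient.
#
# The transform is strict where ingestion was lenient: a coded cell that
# cannot be resolved against its value set aborts the build for that record.
# Missing-data policy: value-bearing Observation elements fall back to the
# standard dataAbsentReason coding "not-provided"; optional elements
# elsewhere are omitted; a resource whose defining code is missing is not
# built (and an auxiliary-only medication group is an error, since a
# MedicationAdministration without an agent is meaningless).

cc_from_coding <- function(cd) {
  coding <- list(system = cd$system, code = cd$code)
  if (!is.null(cd$display)) coding$display <- cd$display
  list(coding = list(coding))
}

quantity_element <- function(value, unit) {
  q <- list(value = value)
  if (!is.null(unit)) q$unit <- unit
  q
}

period_element <- function(period) {
  list(start = format(period$start), end = format(period$end))
}

# Set a dot-separated path inside a resource list ("dosage.dose" nests).
set_element <- function(res, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) {
    res[[parts]] <- value
    return(res)
  }
  node <- res[[parts[1L]]] %||% list()
  node[[parts[2L]]] <- value
  res[[parts[1L]]] <- node
  res
}

element_suffix <- function(vdef) {
  substring(vdef$element_path, nchar(vdef$resource_kind) + 2L)
}

# Convert one resolved (vdef, cell) pair into the element value it populates.
element_value <- function(vdef, cell) {
  reg <- element_registry_lookup(vdef$resource_kind, element_suffix(vdef))
  if (is.null(reg)) {
    stop_oh(sprintf("variable '%s': unsupported element path '%s'",
                    vdef$name, vdef$element_path), "oh_build_error")
  }
  switch(reg$fhir_type,
    CodeableConcept = cc_from_coding(resolve_code(vdef, cell$raw)),
    Identifier = list(list(system = "urn:oncoharmonizer:patient-id",
                           value = cell$raw)),
    code = resolve_code(vdef, cell$raw)$code,
    Quantity = ,
    Age = quantity_element(cell$parsed, vdef$unit),
    integer = cell$parsed,
    string = cell$raw,
    boolean = cell$parsed,
    Period = period_element(recode_interval(cell$parsed)),
    stop_oh(sprintf("variable '%s': no builder for FHIR type '%s'",
                    vdef$name, reg$fhir_type), "oh_build_error")
  )
}

apply_fixed_codings <- function(res, kind, group) {
  for (item in group) {
    for (p in names(item$vdef$fixed_codings)) {
      prefix <- paste0(kind, ".")
      if (!startsWith(p, prefix)) {
        stop_oh(sprintf("fixed coding path '%s' does not address %s", p,
                        kind), "oh_build_error")
      }
      res <- set_element(res, substring(p, nchar(prefix) + 1L),
                         cc_from_coding(item$vdef$fixed_codings[[p]]))
    }
  }
  res
}

#' Build the Patient resource for a record
#'
#' Carries the (already double-hashed) platform patient identifier as an
#' `identifier` element; other patient-level variables populate demographic
#' elements through their dictionary bindings.
#'
#' @param record an `oh_record`.
#' @param schema the governing `oh_schema`.
#' @param urn the resource's `urn:uuid:` identity.
#' @return a resource document (named list ready for JSON).
#' @export
build_patient <- function(record, schema, urn) {
  pvars <- Filter(function(v) identical(v$resource_kind, "Patient"),
                  schema$variables)
  ids <- Filter(function(v) identical(v$role, "identifier"), pvars)
  if (length(ids) == 0L) {
    stop_oh("schema has no patient-identifier variable", "oh_build_error")
  }
  if (length(ids) > 1L) {
    stop_oh(sprintf("record carries multiple patient identifiers (%s)",
                    paste(vapply(ids, `[[`, "", "name"), collapse = ", ")),
            "oh_build_error")
  }
  if (!nzchar(record$patient_id)) {
    stop_oh("record has an empty patient identifier", "oh_build_error")
  }
  res <- list(resourceType = "Patient",
              identifier = list(list(system = "urn:oncoharmonizer:patient-id",
                                     value = record$patient_id)))
  for (v in pvars) {
    if (identical(v$role, "identifier")) next
    cell <- record$cells[[v$name]]
    if (is.null(cell) || cell_is_missing(cell)) next
    res <- set_element(res, element_suffix(v), element_value(v, cell))
  }
  if (!is.null(res$gender) && !res$gender %in% ADMIN_GENDER_CODES) {
    stop_oh(sprintf("Patient.gender code '%s' is not an administrative-gender code",
                    res$gender), "oh_build_error")
  }
  attr(res, "urn") <- urn
  res
}

#' Build a clinical resource from one variable group
#'
#' @param kind `"Condition"`, `"Observation"`, `"Procedure"` or
#'   `"DiagnosticReport"`.
#' @param group list of `list(vdef, cell)` pairs sharing the kind and group.
#' @param subject_urn URN of the bundle's Patient resource.
#' @param urn the resource's URN.
#' @return a resource document, or NULL when the whole group is missing and
#'   the kind tolerates omission.
#' @export
build_clinical_resource <- function(kind, group, subject_urn, urn) {
  stopifnot(kind %in% c("Condition", "Observation", "Procedure",
                        "DiagnosticReport"))
  present <- Filter(function(it) !is.null(it$cell) &&
                      !cell_is_missing(it$cell), group)
  if (kind != "Observation" && length(present) == 0L) return(NULL)

  res <- list(resourceType = kind)
  status <- builder_status_defaults()[[kind]]
  if (!is.null(status)) res[[status$element]] <- status$code
  if (kind == "Condition") {
    cs <- builder_condition_status()
    res$clinicalStatus <- list(coding = list(cs$clinicalStatus))
    res$verificationStatus <- list(coding = list(cs$verificationStatus))
  }
  res <- apply_fixed_codings(res, kind, group)
  res$subject <- list(reference = subject_urn)

  value_paths <- paste0("Observation.value",
                        c("CodeableConcept", "Quantity", "Integer", "String",
                          "Boolean"))
  any_value <- FALSE
  for (it in present) {
    res <- set_element(res, element_suffix(it$vdef),
                       element_value(it$vdef, it$cell))
    if (it$vdef$element_path %in% value_paths) any_value <- TRUE
  }
  if (kind == "Observation") {
    if (is.null(res$code)) {
      stop_oh(sprintf(
        "Observation group '%s' has no fixed Observation.code coding",
        group[[1L]]$vdef$resource_group), "oh_build_error")
    }
    if (!any_value) {
      if (length(present) == 0L) {
        # value not provided: carry the absent-reason coding instead
        res$dataAbsentReason <- list(coding = list(list(
          system = DATA_ABSENT_SYSTEM, code = "not-provided",
          display = "Not Provided")))
      }
    }
  }
  if (kind %in% c("Condition", "Procedure") && is.null(res$code)) {
    stop_oh(sprintf("%s group '%s': defining code element is missing", kind,
                    group[[1L]]$vdef$resource_group), "oh_build_error")
  }
  if (kind == "DiagnosticReport" && is.null(res$code)) {
    stop_oh(sprintf(
      "DiagnosticReport group '%s' has no fixed DiagnosticReport.code",
      group[[1L]]$vdef$resource_group), "oh_build_error")
  }
  attr(res, "urn") <- urn
  res
}

#' Build MedicationAdministration resources from a medication group
#'
#' One resource per agent variable (the resource is designed to carry a
#' single administration entry). Per-dose amount populates `dosage.dose`;
#' total cycles and cumulative dose, which have no native element, are
#' carried as documented extensions; a collected treatment interval is
#' recoded into epoch-anchored dates on `effectivePeriod`, since this
#' resource only accepts calendar dates, not durations.
#'
#' @param group list of `list(vdef, cell)` pairs of the medication group.
#' @param subject_urn URN of the Patient resource.
#' @param urns character vector of URNs, one per agent present.
#' @return list of resource documents (possibly empty).
#' @export
build_medication_administration <- function(group, subject_urn, urns) {
  present <- Filter(function(it) !is.null(it$cell) &&
                      !cell_is_missing(it$cell), group)
  if (length(present) == 0L) return(list())
  is_agent <- vapply(present, function(it)
    identical(element_suffix(it$vdef), "medicationCodeableConcept"), TRUE)
  agents <- present[is_agent]
  aux <- present[!is_agent]
  if (length(agents) == 0L) {
    stop_oh(sprintf(
      "medication group '%s': agent code is missing but dosing facts are present",
      group[[1L]]$vdef$resource_group), "oh_build_error")
  }
  if (length(urns) < length(agents)) {
    stop_oh("not enough URNs supplied for the medication group",
            "oh_build_error")
  }
  lapply(seq_along(agents), function(i) {
    res <- list(resourceType = "MedicationAdministration",
                status = builder_status_defaults(
                )$MedicationAdministration$code)
    res$medicationCodeableConcept <-
      element_value(agents[[i]]$vdef, agents[[i]]$cell)
    res$subject <- list(reference = subject_urn)
    ext <- list()
    for (it in aux) {
      suffix <- element_suffix(it$vdef)
      if (identical(suffix, "extension.totalCycles")) {
        ext[[length(ext) + 1L]] <- list(url = EXT_TOTAL_CYCLES,
                                        valueInteger = it$cell$parsed)
      } else if (identical(suffix, "extension.cumulativeDose")) {
        ext[[length(ext) + 1L]] <- list(
          url = EXT_CUMULATIVE_DOSE,
          valueQuantity = quantity_element(it$cell$parsed, it$vdef$unit))
      } else {
        res <- set_element(res, suffix, element_value(it$vdef, it$cell))
      }
    }
    if (length(ext) > 0L) res$extension <- ext
    attr(res, "urn") <- urns[[i]]
    res
  })
}

# Group non-Patient variables by (resource_kind, resource_group) in first-
# appearance order.
schema_groups <- function(schema) {
  keys <- character(); groups <- list()
  for (v in schema$variables) {
    if (identical(v$resource_kind, "Patient")) next
    key <- paste(v$resource_kind, v$resource_group, sep = "\r")
    if (!key %in% keys) {
      keys <- c(keys, key)
      groups[[key]] <- list(kind = v$resource_kind,
                            group = v$resource_group, vars = list())
    }
    groups[[key]]$vars <- c(groups[[key]]$vars, list(v))
  }
  groups
}

#' Predict per-kind resource counts for a fully observed record
#'
#' The census implied by the dictionary grouping alone: one Patient plus one
#' resource per (kind, group) — medication groups contribute one resource per
#' agent variable. Used as an independent expectation for emitted bundles.
#'
#' @param schema an `oh_schema`.
#' @return named integer vector, one entry per resource kind present.
#' @export
resource_census <- function(schema) {
  counts <- c(Patient = 1L)
  for (g in schema_groups(schema)) {
    n <- if (identical(g$kind, "MedicationAdministration")) {
      sum(vapply(g$vars, function(v)
        identical(element_suffix(v), "medicationCodeableConcept"), TRUE))
    } else 1L
    counts[g$kind] <- (if (is.na(counts[g$kind])) 0L else counts[g$kind]) +
      as.integer(n)
  }
  counts[!is.na(counts) & counts > 0L]
}

#' Map one patient record to a FHIR bundle
#'
#' Groups the record's variables by their dictionary bindings and builds one
#' resource per group (Patient first), wiring subject references and URN
#' identities. With a seeded `id_factory` the transform is fully
#' deterministic.
#'
#' @param record an `oh_record` that passed ingestion.
#' @param schema the governing `oh_schema`.
#' @param id_factory a [make_id_factory()] (seeded for reproducible output).
#' @return object of class `oh_bundle` (JSON-ready named list).
#' @export
map_record_to_bundle <- function(record, schema,
                                 id_factory = make_id_factory()) {
  stopifnot(inherits(record, "oh_record"), inherits(schema, "oh_schema"))
  bundle_urn <- paste0("urn:uuid:", id_factory())
  patient_urn <- paste0("urn:uuid:", id_factory())
  patient <- build_patient(record, schema, patient_urn)
  entries <- list(list(fullUrl = patient_urn,
                       resource = strip_urn(patient)))
  for (g in schema_groups(schema)) {
    items <- lapply(g$vars, function(v)
      list(vdef = v, cell = record$cells[[v$name]]))
    if (identical(g$kind, "MedicationAdministration")) {
      n_agents <- sum(vapply(items, function(it)
        !is.null(it$cell) && !cell_is_missing(it$cell) &&
          identical(element_suffix(it$vdef), "medicationCodeableConcept"),
        TRUE))
      urns <- vapply(seq_len(n_agents), function(i)
        paste0("urn:uuid:", id_factory()), "")
      for (res in build_medication_administration(items, patient_urn, urns)) {
        entries[[length(entries) + 1L]] <-
          list(fullUrl = attr(res, "urn"), resource = strip_urn(res))
      }
    } else {
      urn <- paste0("urn:uuid:", id_factory())
      res <- build_clinical_resource(g$kind, items, patient_urn, urn)
      if (!is.null(res)) {
        entries[[length(entries) + 1L]] <-
          list(fullUrl = urn, resource = strip_urn(res))
      }
    }
  }
  structure(
    list(resourceType = "Bundle",
         identifier = list(system = "urn:ietf:rfc:3986", value = bundle_urn),
         type = "collection",
         entry = entries),
    class = "oh_bundle"
  )
}

strip_urn <- function(res) {
  attr(res, "urn") <- NULL
  res
}

#' Serialize a bundle to its per-patient JSON file
#'
#' One file per patient, named by the platform patient hash, with
#' deterministic key order; `serialize -> parse -> serialize` is
#' byte-identical.
#'
#' @param bundle an `oh_bundle`.
#' @param out_dir output directory (created if absent).
#' @return the written file path, invisibly.
#' @export
serialize_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "oh_bundle") || is.list(bundle))
  pid <- bundle$entry[[1L]]$resource$identifier[[1L]]$value
  if (is.null(pid) || !nzchar(pid)) {
    stop_oh("bundle's Patient entry carries no identifier", "oh_build_error")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, paste0(pid, ".json"))
  json <- jsonlite::toJSON(unclass(bundle), auto_unbox = TRUE, digits = NA,
                           pretty = 2)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Parse a bundle file back into an `oh_bundle`
#'
#' @param path JSON file path.
#' @return object of class `oh_bundle`.
#' @export
read_bundle <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(doc, class = "oh_bundle")
}

#' Transform a cohort into bundle files
#'
#' @param records list of `oh_record`.
#' @param schema the governing `oh_schema`.
#' @param out_dir output directory.
#' @param seed optional integer seed for reproducible URNs.
#' @param lenient when TRUE, records that fail the strict transform are
#'   skipped (reported in the result) instead of aborting the whole run.
#' @return list(files, skipped) — written paths and a data.frame of skipped
#'   patients with reasons.
#' @export
transform_cohort <- function(records, schema, out_dir, seed = NULL,
                             lenient = FALSE) {
  idf <- make_id_factory(seed)
  files <- character()
  skipped <- data.frame(patient_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (rec in records) {
    bundle <- tryCatch(
      map_record_to_bundle(rec, schema, idf),
      oh_error = function(e) e
    )
    if (inherits(bundle, "oh_error")) {
      if (!lenient) stop(bundle)
      skipped <- rbind(skipped, data.frame(patient_id = rec$patient_id,
                                           reason = conditionMessage(bundle),
                                           stringsAsFactors = FALSE))
      next
    }
    files <- c(files, serialize_bundle(bundle, out_dir))
  }
  list(files = files, skipped = skipped)
}
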