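# Built-in demonstration schemas.
#
# These are synthetic, representative study schemas (the production
# dictionaries of a real consortium are not public); variable rosters and
# value sets are invented but structurally faithful: three requirement
# tiers, mixed datatypes, ontology-coded value sets with an "other"
# sentinel carried as a SNOMED post-coordinated expression.
#
# scorecard_demo_schemas()/scorecard_demo_cohort() define the worked
# quality-scoring example used throughout the documentation: a pooled
# cohort over two schemas (4 + 3 records) whose injected defects yield the
# reference scorecard
#   minimal_req 2/18, mandatory_req 3/35, length 1/11, datatype 0/40,
#   permissible 3/55, range 1/4, total 10/163, score 89.63%.
# Two schemas are required: completeness checks always execute, so the two
# completeness totals must be n*m and n*(m+d) for a single schema of m
# minimal and d mandatory variables — and 18 and 35 are coprime, forcing a
# pooled design.

vs2 <- function(system, c1, l1, c2, l2, other = FALSE) {
  vs <- list(
    value_set_entry("1", l1, coding(system, c1, l1)),
    value_set_entry("2", l2, coding(system, c2, l2))
  )
  if (other) {
    vs[[3L]] <- value_set_entry(
      "OTHER", "Other",
      coding(SYSTEM_SNOMED,
             "261665006:246090004=74964007 |Other|", "Other (grouped)"),
      sentinel = TRUE)
  }
  vs
}

obs_code <- function(code, display) {
  list("Observation.code" = coding(SYSTEM_LOINC, code, display))
}

report_code <- function(code, display) {
  list("DiagnosticReport.code" = coding(SYSTEM_LOINC, code, display))
}

# Shorthand constructors used only for the demo rosters.
demo_var <- function(schema_id, name, level, datatype, kind, path, ...) {
  variable_definition(name = name, schema_id = schema_id,
                      requirement_level = level, datatype = datatype,
                      resource_kind = kind, element_path = path, ...)
}

scorecard_schema_a <- function() {
  sid <- "demo_breast_neoadjuvant"
  v <- function(...) demo_var(sid, ...)
  obs_cc <- function(name, level, loinc, display, vs, group = NULL) {
    v(name, level, "code", "Observation", "Observation.valueCodeableConcept",
      value_set = vs, fixed_codings = obs_code(loinc, display),
      resource_group = group)
  }
  schema_definition(sid, use_cases = "breast_neoadjuvant_response", list(
    v("patient_id", "minimal", "string", "Patient", "Patient.identifier",
      role = "identifier"),
    # minimal tier: ground-truth pathology fields
    v("diagnosis_code", "minimal", "code", "Condition", "Condition.code",
      value_set = vs2(SYSTEM_SNOMED, "254837009",
                      "Malignant tumor of breast", "92691004",
                      "Benign neoplasm of breast"),
      resource_group = "diagnosis"),
    v("pathology_note", "minimal", "string", "DiagnosticReport",
      "DiagnosticReport.conclusion", resource_group = "pathology_summary",
      fixed_codings = report_code("22637-3", "Pathology report")),
    v("response_note", "minimal", "string", "DiagnosticReport",
      "DiagnosticReport.conclusion", resource_group = "response_summary",
      fixed_codings = report_code("59847-4", "Pathology synoptic report")),
    # mandatory tier
    v("tumor_grade", "mandatory", "code", "Observation",
      "Observation.valueCodeableConcept",
      value_set = vs2(SYSTEM_NCIT, "C28077", "Grade 1", "C28078", "Grade 2",
                      other = TRUE),
      fixed_codings = obs_code("33732-9", "Histology grade")),
    v("age_at_diagnosis", "mandatory", "integer", "Condition",
      "Condition.onsetAge", range = c(18, 100), unit = "years",
      resource_group = "diagnosis"),
    # recommended tier
    obs_cc("er_status", "recommended", "16112-5", "Estrogen receptor status",
           vs2(SYSTEM_SNOMED, "10828004", "Positive", "260385009",
               "Negative")),
    obs_cc("pr_status", "recommended", "16113-3",
           "Progesterone receptor status",
           vs2(SYSTEM_SNOMED, "10828004", "Positive", "260385009",
               "Negative")),
    obs_cc("her2_status", "recommended", "48676-1", "HER2 status",
           vs2(SYSTEM_SNOMED, "10828004", "Positive", "260385009",
               "Negative")),
    obs_cc("menopausal_status", "recommended", "42802-9",
           "Menopausal status",
           vs2(SYSTEM_NCIT, "C15491", "Premenopausal", "C15421",
               "Postmenopausal", other = TRUE)),
    obs_cc("response_category", "recommended", "21976-6",
           "Treatment response",
           vs2(SYSTEM_NCIT, "C123557", "Complete response", "C123584",
               "Partial response", other = TRUE)),
    v("histology_code", "recommended", "code", "DiagnosticReport",
      "DiagnosticReport.conclusionCode",
      value_set = vs2(SYSTEM_ICDO3, "8500/3", "Ductal carcinoma NOS",
                      "8520/3", "Lobular carcinoma NOS"),
      resource_group = "pathology_report",
      fixed_codings = report_code("22637-3", "Pathology report")),
    v("surgery_type", "recommended", "code", "Procedure", "Procedure.code",
      value_set = vs2(SYSTEM_SNOMED, "69031006", "Mastectomy", "392021009",
                      "Lumpectomy"),
      resource_group = "surgery"),
    v("chemo_agent", "recommended", "code", "MedicationAdministration",
      "MedicationAdministration.medicationCodeableConcept",
      value_set = vs2(SYSTEM_RXNORM, "3639", "Doxorubicin", "56946",
                      "Paclitaxel"),
      resource_group = "chemo"),
    v("chemo_cycles", "recommended", "integer", "MedicationAdministration",
      "MedicationAdministration.extension.totalCycles",
      resource_group = "chemo"),
    v("tumor_size_mm", "recommended", "decimal", "Observation",
      "Observation.valueQuantity", unit = "mm",
      fixed_codings = obs_code("21889-1", "Tumor size")),
    v("ki67_percent", "recommended", "decimal", "Observation",
      "Observation.valueQuantity", unit = "%",
      fixed_codings = obs_code("85319-2", "Ki-67 fraction")),
    v("time_to_surgery", "recommended", "interval", "Procedure",
      "Procedure.performedPeriod", resource_group = "surgery"),
    v("followup_time", "recommended", "interval", "Observation",
      "Observation.effectivePeriod",
      fixed_codings = obs_code("67505-7", "Follow-up interval")),
    v("node_positive", "recommended", "boolean", "Observation",
      "Observation.valueBoolean",
      fixed_codings = obs_code("21893-3", "Regional lymph node status")),
    v("center_code", "recommended", "string", "Observation",
      "Observation.valueString", max_length = 8,
      fixed_codings = obs_code("74211-3", "Reporting center")),
    v("histology_freetext", "recommended", "string", "DiagnosticReport",
      "DiagnosticReport.conclusion", max_length = 40,
      resource_group = "pathology_report",
      fixed_codings = report_code("22637-3", "Pathology report"))
  ))
}

scorecard_schema_b <- function() {
  sid <- "demo_colorectal_screen"
  v <- function(...) demo_var(sid, ...)
  obs_cc <- function(name, level, loinc, display, vs) {
    v(name, level, "code", "Observation", "Observation.valueCodeableConcept",
      value_set = vs, fixed_codings = obs_code(loinc, display))
  }
  schema_definition(sid, use_cases = "colorectal_lesion_screen", list(
    v("patient_id", "minimal", "string", "Patient", "Patient.identifier",
      role = "identifier"),
    v("diagnosis_code", "minimal", "code", "Condition", "Condition.code",
      value_set = vs2(SYSTEM_SNOMED, "363406005",
                      "Malignant tumor of colon", "428054006",
                      "Benign neoplasm of colon"),
      resource_group = "diagnosis"),
    obs_cc("lesion_type", "minimal", "33756-8", "Lesion type",
           vs2(SYSTEM_SNOMED, "128477000", "Polyp", "108369006", "Neoplasm",
               other = TRUE)),
    obs_cc("t_stage", "mandatory", "21905-5", "Primary tumor category",
           vs2(SYSTEM_NCIT, "C48720", "T1", "C48724", "T2", other = TRUE)),
    v("lesion_size_mm", "mandatory", "decimal", "Observation",
      "Observation.valueQuantity", unit = "mm",
      fixed_codings = obs_code("33728-7", "Lesion size")),
    v("radiology_note", "mandatory", "string", "DiagnosticReport",
      "DiagnosticReport.conclusion", resource_group = "radiology_report",
      fixed_codings = report_code("18748-4", "Diagnostic imaging report")),
    obs_cc("n_stage", "recommended", "21906-3", "Regional node category",
           vs2(SYSTEM_NCIT, "C48705", "N0", "C48706", "N1")),
    obs_cc("m_stage", "recommended", "21907-1", "Distant metastasis category",
           vs2(SYSTEM_NCIT, "C48699", "M0", "C48700", "M1")),
    v("age", "recommended", "integer", "Condition", "Condition.onsetAge",
      unit = "years", resource_group = "diagnosis"),
    v("lesion_count", "recommended", "integer", "Observation",
      "Observation.valueInteger",
      fixed_codings = obs_code("33757-6", "Lesion count")),
    v("screening_interval", "recommended", "interval", "Observation",
      "Observation.effectivePeriod",
      fixed_codings = obs_code("67506-5", "Screening interval")),
    v("center_code", "recommended", "string", "Observation",
      "Observation.valueString", max_length = 8,
      fixed_codings = obs_code("74211-3", "Reporting center"))
  ))
}

#' The two demonstration schemas behind the worked scorecard example
#'
#' A 21-variable breast-cancer schema (4-record sub-cohort) and an
#' 11-variable colorectal schema (3-record sub-cohort). Pooled and
#' fault-injected by [scorecard_demo_cohort()], they reproduce the reference
#' scoring report exactly (10 fails / 153 passes / 163 checks, total score
#' 89.63%).
#'
#' @return named list of two `oh_schema` objects.
#' @export
scorecard_demo_schemas <- function() {
  schemas <- list(scorecard_schema_a(), scorecard_schema_b())
  names(schemas) <- vapply(schemas, `[[`, "", "schema_id")
  schemas
}

#' Build the worked-example cohort with its injected defects
#'
#' Generates 4 + 3 fully compliant records over the two demo schemas and
#' injects exactly: 2 missing minimal cells, 1 further missing mandatory
#' cell (3 mandatory fails in total), 1 overlong string, 3 out-of-set codes
#' and 1 out-of-range number. Completeness blanks are restricted to
#' free-text variables that carry no conformance rules, so each defect
#' perturbs exactly one check type and the executed-check totals stay at
#' 18/35/11/40/55/4.
#'
#' @param seed integer seed for generation and site selection.
#' @return list(records, schemas, rules, log): the pooled defective cohort,
#'   the schemas, the concatenated QC rules, and the injection log.
#' @export
scorecard_demo_cohort <- function(seed = 20260101L) {
  schemas <- scorecard_demo_schemas()
  a <- generate_cohort(schemas[[1L]], 4L, seed = seed)
  b <- generate_cohort(schemas[[2L]], 3L, seed = seed + 1L)
  records <- c(a, b)
  inj <- inject_errors(
    records,
    spec = list(
      minimal_req = list(count = 2,
                         variables = c("pathology_note", "response_note")),
      mandatory_req = list(count = 3, variables = "radiology_note"),
      length = 1,
      permissible = 3,
      range = 1
    ),
    schemas = schemas, seed = seed + 2L
  )
  rules <- c(compile_rules(schemas[[1L]]), compile_rules(schemas[[2L]]))
  list(records = inj$records, schemas = schemas, rules = rules,
       log = inj$log)
}
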