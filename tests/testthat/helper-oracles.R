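# Independent oracles and small fixtures used across the suite.

# Naive per-cell quality evaluation, written directly from the variable
# definitions and deliberately independent of compile_rules()/run_qc():
# its own missingness handling, its own parse checks. Returns one row per
# executed check.
brute_force_qc <- function(records, schemas) {
  if (inherits(schemas, "oh_schema")) schemas <- list(schemas)
  names(schemas) <- vapply(schemas, function(s) s$schema_id, "")
  out <- list()
  emit <- function(pid, var, type, ok) {
    out[[length(out) + 1L]] <<- data.frame(
      patient_id = pid, variable = var, rule_type = type,
      outcome = if (ok) "pass" else "fail", stringsAsFactors = FALSE)
  }
  looks_like <- function(raw, datatype) {
    switch(datatype,
      integer = grepl("^[+-]?[0-9]+$", raw),
      decimal = !is.na(suppressWarnings(as.numeric(raw))),
      boolean = tolower(raw) %in% c("0", "1", "true", "false"),
      interval = {
        p <- strsplit(raw, " ", fixed = TRUE)[[1]]
        length(p) == 2 && grepl("^[0-9]+$", p[1]) &&
          p[2] %in% c("days", "weeks", "months")
      })
  }
  for (rec in records) {
    schema <- schemas[[rec$schema_id]]
    for (v in schema$variables) {
      if (identical(v$role, "identifier")) next
      cell <- rec$cells[[v$name]]
      raw <- if (is.null(cell)) "" else cell$raw
      missing <- !nzchar(raw)
      if (identical(v$requirement_level, "minimal")) {
        emit(rec$patient_id, v$name, "minimal_req", !missing)
      }
      if (v$requirement_level %in% c("minimal", "mandatory")) {
        emit(rec$patient_id, v$name, "mandatory_req", !missing)
      }
      if (missing) next
      if (!is.null(v$max_length)) {
        emit(rec$patient_id, v$name, "length", nchar(raw) <= v$max_length)
      }
      if (v$datatype %in% c("integer", "decimal", "interval", "boolean")) {
        emit(rec$patient_id, v$name, "datatype", looks_like(raw, v$datatype))
      }
      if (identical(v$datatype, "code")) {
        codes <- vapply(v$value_set, function(e) e$internal_code, "")
        emit(rec$patient_id, v$name, "permissible", raw %in% codes)
      }
      if (!is.null(v$range)) {
        x <- suppressWarnings(as.numeric(raw))
        if (!is.na(x)) {
          emit(rec$patient_id, v$name, "range",
               x >= v$range[1] && x <= v$range[2])
        }
      }
    }
  }
  do.call(rbind, out)
}

# Canonical ordering so finding frames can be compared as sets.
sort_findings <- function(df) {
  df <- df[order(df$patient_id, df$variable, df$rule_type, df$outcome), ]
  rownames(df) <- NULL
  df
}

demo_schema <- function() load_dictionary(oh_example("breast_demo.yaml"))

# A tiny two-variable schema (identifier + one coded variable).
tiny_schema <- function(level = "minimal") {
  schema_definition("tiny", list(
    variable_definition("patient_id", "tiny", "minimal", "string", "Patient",
                        "Patient.identifier", role = "identifier"),
    variable_definition(
      "biological_sex", "tiny", level, "code", "Patient", "Patient.gender",
      value_set = list(
        value_set_entry("1", "Female",
                        coding("http://hl7.org/fhir/administrative-gender",
                               "female", "Female")),
        value_set_entry("2", "Male",
                        coding("http://hl7.org/fhir/administrative-gender",
                               "male", "Male"))))
  ))
}

# Build a record for a schema directly from raw strings.
record_from_raw <- function(schema, raw, patient_id = "p1") {
  cells <- list()
  for (v in schema$variables) {
    r <- raw[[v$name]]
    if (identical(v$role, "identifier")) r <- patient_id
    cells[[v$name]] <- parse_cell(r %||% "", v)
  }
  oncoharmonizer:::new_record(patient_id, schema$schema_id, cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
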