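test_that("the smallest legal dictionary loads with order preserved", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "schema_id: mini",
    "variables:",
    "  - name: patient_id",
    "    role: identifier",
    "    requirement_level: minimal",
    "    datatype: string",
    "    resource_kind: Patient",
    "    element_path: Patient.identifier",
    "  - name: biological_sex",
    "    requirement_level: minimal",
    "    datatype: code",
    "    resource_kind: Patient",
    "    element_path: Patient.gender",
    "    value_set:",
    "      - internal_code: '1'",
    "        label: Female",
    "        system: 'http://hl7.org/fhir/administrative-gender'",
    "        code: female"
  ), path)
  schema <- load_dictionary(path)
  expect_s3_class(schema, "oh_schema")
  expect_length(schema$variables, 2L)
  expect_identical(names(schema$variables), c("patient_id", "biological_sex"))
})

test_that("a coded variable without a value set is refused with a named violation", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "schema_id: broken",
    "variables:",
    "  - name: patient_id",
    "    role: identifier",
    "    requirement_level: minimal",
    "    datatype: string",
    "    resource_kind: Patient",
    "    element_path: Patient.identifier",
    "  - name: grade",
    "    requirement_level: mandatory",
    "    datatype: code",
    "    resource_kind: Observation",
    "    element_path: Observation.valueCodeableConcept"
  ), path)
  err <- expect_error(load_dictionary(path), class = "oh_dictionary_error")
  expect_match(conditionMessage(err), "grade")
  expect_match(conditionMessage(err), "value set")
})

test_that("parse failures name the file and problem", {
  path <- tempfile(fileext = ".yaml")
  writeLines("variables: [", path)
  expect_error(load_dictionary(path), class = "oh_format_error")
  path2 <- tempfile(fileext = ".yaml")
  writeLines(c("schema_id: x", "variables:", "  - name: v"), path2)
  err <- expect_error(load_dictionary(path2), class = "oh_format_error")
  expect_match(conditionMessage(err), "requirement_level")
})

test_that("the shipped demo schema matches an independent scan of its file", {
  schema <- demo_schema()
  # independent scan: raw YAML, counted without the dictionary model
  doc <- yaml::read_yaml(oh_example("breast_demo.yaml"))
  kinds <- vapply(doc$variables, function(v) v$resource_kind, "")
  expect_length(schema$variables, length(doc$variables))
  loaded_kinds <- vapply(schema$variables, function(v) v$resource_kind, "")
  expect_identical(c(table(loaded_kinds)), c(table(kinds)))
  expect_setequal(unique(kinds),
                  c("Patient", "Condition", "Observation", "Procedure",
                    "MedicationAdministration", "DiagnosticReport"))
  expect_length(validate_dictionary(schema), 0L)
})

test_that("validate_dictionary reports every violation, not just the first", {
  schema <- schema_definition("bad", list(
    variable_definition("patient_id", "bad", "minimal", "string", "Patient",
                        "Patient.identifier", role = "identifier"),
    variable_definition("age", "bad", "mandatory", "integer", "Condition",
                        "Condition.onsetAge", range = c(5, 1)),
    variable_definition("odd", "bad", "recommended", "decimal", "Observation",
                        "Observation.bogusElement")
  ))
  v <- validate_dictionary(schema)
  expect_length(v, 2L)
  expect_match(v[grepl("age", v)], "range")
  expect_match(v[grepl("odd", v)], "not a supported")
})

test_that("element paths are checked against the structural subset", {
  expect_true(check_element_path("Observation", "Observation.valueQuantity",
                                 "decimal"))
  expect_match(check_element_path("Observation", "Observation.bogusElement"),
               "not a supported")
  expect_match(check_element_path("Observation", "Patient.gender"),
               "does not address")
  expect_match(check_element_path("Observation", "Observation.valueQuantity",
                                  "code"), "does not accept")
})

test_that("dictionary serialization round-trips exactly", {
  schema <- demo_schema()
  out <- tempfile(fileext = ".yaml")
  serialize_dictionary(schema, out)
  expect_identical(load_dictionary(out), schema)

  prog <- scorecard_demo_schemas()[[1L]]
  out2 <- tempfile(fileext = ".yaml")
  serialize_dictionary(prog, out2)
  expect_identical(load_dictionary(out2), prog)
})

test_that("the loader is at least as strict as the validator", {
  for (f in c("breast_demo.yaml")) {
    expect_length(validate_dictionary(load_dictionary(oh_example(f))), 0L)
  }
})

test_that("resolve_code is a total lookup with a strict error contract", {
  schema <- demo_schema()
  sex <- schema$variables$biological_sex
  expect_identical(resolve_code(sex, "1")$code, "female")

  hist <- schema$variables$histology
  other <- resolve_code(hist, "OTHER")
  expect_identical(other$system, "http://snomed.info/sct")
  expect_match(other$code, ":")  # post-coordinated expression

  err <- expect_error(resolve_code(sex, "9"),
                      class = "oh_unmapped_value_error")
  expect_match(conditionMessage(err), "biological_sex")
  expect_match(conditionMessage(err), "'9'")
})

test_that("the terminology registry is closed and SNOMED-only for expressions", {
  expect_error(coding("http://example.org/unregistered", "1"),
               class = "oh_terminology_error")
  expect_error(coding("http://loinc.org", "a:b=c"),
               class = "oh_terminology_error")
  expect_error(coding("http://snomed.info/sct", ""),
               class = "oh_terminology_error")
  expect_silent(coding("http://snomed.info/sct", "12345:67=89"))
})
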