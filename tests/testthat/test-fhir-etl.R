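patient_only_schema <- function() tiny_schema("minimal")

test_that("a record with only patient-level fields becomes a one-resource bundle", {
  schema <- patient_only_schema()
  rec <- record_from_raw(schema, list(biological_sex = "1"))
  bundle <- map_record_to_bundle(rec, schema, make_id_factory(1L))
  expect_identical(bundle$resourceType, "Bundle")
  expect_identical(bundle$type, "collection")
  expect_length(bundle$entry, 1L)
  patient <- bundle$entry[[1L]]$resource
  expect_identical(patient$resourceType, "Patient")
  expect_identical(patient$gender, "female")
  expect_identical(patient$identifier[[1L]]$value, "p1")
})

test_that("a full demo record produces the dictionary-predicted census with resolving references", {
  schema <- demo_schema()
  rec <- generate_cohort(schema, 1L, seed = 5L)[[1L]]
  bundle <- map_record_to_bundle(rec, schema, make_id_factory(2L))
  kinds <- vapply(bundle$entry, function(e) e$resource$resourceType, "")
  census <- resource_census(schema)
  expect_identical(table(factor(kinds, levels = names(census))),
                   table(factor(rep(names(census), census),
                                levels = names(census))))
  expect_identical(kinds[1L], "Patient")
  patient_urn <- bundle$entry[[1L]]$fullUrl
  for (e in bundle$entry[-1L]) {
    expect_identical(e$resource$subject$reference, patient_urn)
  }
  urns <- vapply(bundle$entry, function(e) e$fullUrl, "")
  expect_identical(anyDuplicated(urns), 0L)
  expect_true(all(grepl("^urn:uuid:", urns)))
})

test_that("case/control classification lands on Condition, not Observation", {
  schema <- demo_schema()
  rec <- record_from_raw(schema, list(case_control = "2",
                                      age_at_diagnosis = "61"))
  bundle <- map_record_to_bundle(rec, schema, make_id_factory(3L))
  kinds <- vapply(bundle$entry, function(e) e$resource$resourceType, "")
  cond <- bundle$entry[[which(kinds == "Condition")]]$resource
  # the control (benign) arm is still a Condition, associated with onset age
  expect_identical(cond$code$coding[[1L]]$code, "92691004")
  expect_identical(cond$code$coding[[1L]]$system, "http://snomed.info/sct")
  expect_identical(cond$onsetAge$value, 61)
  expect_identical(cond$onsetAge$unit, "years")
  expect_false(any(vapply(bundle$entry, function(e) {
    r <- e$resource
    r$resourceType == "Observation" &&
      !is.null(r$valueCodeableConcept) &&
      r$valueCodeableConcept$coding[[1L]]$code %in% c("254837009", "92691004")
  }, TRUE)))
})

test_that("a missing Observation value is carried as dataAbsentReason", {
  schema <- demo_schema()
  rec <- record_from_raw(schema, list(case_control = "1", er_status = ""))
  bundle <- map_record_to_bundle(rec, schema, make_id_factory(4L))
  obs <- Filter(function(e) e$resource$resourceType == "Observation",
                bundle$entry)
  er <- Filter(function(e)
    e$resource$code$coding[[1L]]$code == "16112-5", obs)
  expect_length(er, 1L)
  r <- er[[1L]]$resource
  expect_null(r$valueCodeableConcept)
  expect_identical(r$dataAbsentReason$coding[[1L]]$code, "not-provided")
  expect_identical(r$status, "final")
})

test_that("wholly missing non-Observation groups are omitted", {
  schema <- demo_schema()
  rec <- record_from_raw(schema, list(case_control = "1"))
  bundle <- map_record_to_bundle(rec, schema, make_id_factory(5L))
  kinds <- vapply(bundle$entry, function(e) e$resource$resourceType, "")
  expect_false("Procedure" %in% kinds)
  expect_false("MedicationAdministration" %in% kinds)
  expect_false("DiagnosticReport" %in% kinds)
})

test_that("medication groups recode treatment intervals onto epoch dates", {
  schema <- demo_schema()
  rec <- record_from_raw(schema, list(case_control = "1", chemo_agent = "1",
                                      chemo_cycles = "6",
                                      treatment_interval = "4 months"))
  bundle <- map_record_to_bundle(rec, schema, make_id_factory(6L))
  kinds <- vapply(bundle$entry, function(e) e$resource$resourceType, "")
  med <- bundle$entry[[which(kinds == "MedicationAdministration")]]$resource
  expect_identical(med$medicationCodeableConcept$coding[[1L]]$code, "3639")
  expect_identical(med$effectivePeriod$start, "1970-01-01")
  expect_identical(med$effectivePeriod$end, "1970-05-01")
  cycles <- Filter(function(x)
    x$url == "urn:oncoharmonizer:extension:total-cycles", med$extension)
  expect_length(cycles, 1L)
  expect_identical(cycles[[1L]]$valueInteger, 6)
  expect_identical(med$status, "completed")
})

test_that("one medication resource is built per agent, and an agentless group errors", {
  schema <- demo_schema()
  agent <- schema$variables$chemo_agent
  cycles <- schema$variables$chemo_cycles
  mk <- function(vdef, raw) list(vdef = vdef, cell = parse_cell(raw, vdef))
  # agent only: minimal valid resource, no extensions
  res <- build_medication_administration(list(mk(agent, "2")), "urn:uuid:x",
                                         "urn:uuid:a")
  expect_length(res, 1L)
  expect_null(res[[1L]]$extension)
  # two agents: two resources, shared aux facts
  res2 <- build_medication_administration(
    list(mk(agent, "1"), mk(agent, "2"), mk(cycles, "4")),
    "urn:uuid:x", c("urn:uuid:a", "urn:uuid:b"))
  expect_length(res2, 2L)
  expect_identical(res2[[1L]]$extension[[1L]]$valueInteger, 4)
  # dosing facts without an agent are refused
  expect_error(build_medication_administration(list(mk(cycles, "4")),
                                               "urn:uuid:x", "urn:uuid:a"),
               class = "oh_build_error")
})

test_that("the transform is strict on unmapped codes, lenient only on request", {
  schema <- demo_schema()
  good <- generate_cohort(schema, 2L, seed = 8L)
  bad <- good
  bad[[2L]]$cells$er_status <- parse_cell("99", schema$variables$er_status)
  out <- tempfile()
  expect_error(transform_cohort(bad, schema, out),
               class = "oh_unmapped_value_error")
  # strict failure leaves no partial file for the offending patient
  expect_false(file.exists(file.path(out, paste0(bad[[2L]]$patient_id,
                                                 ".json"))))
  res <- transform_cohort(bad, schema, out, lenient = TRUE)
  expect_length(res$files, 1L)
  expect_identical(res$skipped$patient_id, bad[[2L]]$patient_id)
})

test_that("serialization is deterministic, parseable, and byte-stable", {
  schema <- demo_schema()
  recs <- generate_cohort(schema, 4L, seed = 12L)
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- transform_cohort(recs, schema, d1, seed = 33L)
  r2 <- transform_cohort(recs, schema, d2, seed = 33L)
  expect_length(r1$files, 4L)
  for (i in seq_along(r1$files)) {
    expect_identical(readLines(r1$files[i]), readLines(r2$files[i]))
  }
  b <- read_bundle(r1$files[1L])
  expect_identical(b$resourceType, "Bundle")
  again <- serialize_bundle(b, tempfile())
  expect_identical(readBin(r1$files[1L], "raw", file.size(r1$files[1L])),
                   readBin(again, "raw", file.size(again)))
  # a different seed yields different URNs but the same clinical content
  d3 <- tempfile()
  r3 <- transform_cohort(recs, schema, d3, seed = 34L)
  expect_false(identical(readLines(r1$files[1L]), readLines(r3$files[1L])))
})

test_that("a schema with two identifier variables is refused at build time", {
  sid <- "dup"
  schema <- schema_definition(sid, list(
    variable_definition("patient_id", sid, "minimal", "string", "Patient",
                        "Patient.identifier", role = "identifier"),
    variable_definition("legacy_id", sid, "minimal", "string", "Patient",
                        "Patient.identifier", role = "identifier")
  ))
  rec <- record_from_raw(schema, list(), "px")
  expect_error(build_patient(rec, schema, "urn:uuid:x"),
               class = "oh_build_error")
})
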