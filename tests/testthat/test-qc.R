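test_that("rule compilation follows the per-variable applicability table", {
  # one minimal coded variable: both completeness rules + permissible; a
  # coded cell carries no parse constraint, so no datatype rule
  rules <- compile_rules(tiny_schema("minimal"))
  expect_identical(sort(vapply(rules, function(r) r$rule_type, "")),
                   sort(c("minimal_req", "mandatory_req", "permissible")))

  # recommended decimal with range: datatype + range only
  sid <- "r1"
  schema <- schema_definition(sid, list(
    variable_definition("patient_id", sid, "minimal", "string", "Patient",
                        "Patient.identifier", role = "identifier"),
    variable_definition("ki67", sid, "recommended", "decimal", "Observation",
                        "Observation.valueQuantity", range = c(0, 100))
  ))
  rules <- compile_rules(schema)
  expect_identical(sort(vapply(rules, function(r) r$rule_type, "")),
                   c("datatype", "range"))

  # demo schema: hand tally from the dictionary fixture
  expect_length(compile_rules(demo_schema()), 24L)
})

test_that("each rule type maps to its fixed quality dimension", {
  rules <- compile_rules(demo_schema())
  dims <- vapply(rules, function(r) r$dimension, "")
  types <- vapply(rules, function(r) r$rule_type, "")
  expect_true(all(dims[types %in% c("minimal_req", "mandatory_req")] ==
                    "Completeness"))
  expect_true(all(dims[types %in% c("length", "datatype", "permissible")] ==
                    "Conformance"))
  expect_true(all(dims[types == "range"] == "Plausibility"))
})

test_that("a fully compliant cohort scores 100.00 with zero fails", {
  schema <- demo_schema()
  recs <- generate_cohort(schema, 10L, seed = 3L)
  rep <- run_qc(recs, compile_rules(schema))
  expect_identical(rep$total_fail, 0)
  expect_equal(rep$total_score_display, 100)
})

test_that("a blank minimal cell fails both completeness requirements and nothing else", {
  schema <- demo_schema()
  recs <- generate_cohort(schema, 3L, seed = 4L)
  recs[[2L]]$cells$case_control <- parse_cell("", schema$variables$case_control)
  rep <- run_qc(recs, compile_rules(schema))
  fails <- rep$findings[rep$findings$outcome == "fail", ]
  # minimal is a fortiori mandatory: one blank, two completeness findings
  expect_identical(sort(fails$rule_type), c("mandatory_req", "minimal_req"))
  expect_true(all(fails$variable == "case_control"))
  # the blank cell is skipped by conformance: no permissible finding for it
  perm <- rep$findings[rep$findings$rule_type == "permissible", ]
  expect_false(any(perm$patient_id == recs[[2L]]$patient_id &
                     perm$variable == "case_control"))
})

test_that("dimension scoring reproduces the reference report rows", {
  expect_equal(score_dimension(2, 16, 50), 44.44)
  expect_equal(score_dimension(3, 32, 10), 9.14)
  expect_equal(score_dimension(1, 10, 10), 9.09)
  expect_equal(score_dimension(0, 40, 10), 10.00)
  expect_equal(score_dimension(3, 52, 10), 9.45)
  expect_equal(score_dimension(1, 3, 10), 7.50)
  # zero executed checks keep their full weight (vacuous satisfaction)
  expect_equal(score_dimension(0, 0, 10), 10.00)
})

test_that("aggregation sums unrounded terms and rounds once", {
  tallies <- data.frame(
    fail = c(2, 3, 1, 0, 3, 1), pass = c(16, 32, 10, 40, 52, 3),
    weight = c(50, 10, 10, 10, 10, 10))
  tot <- aggregate_report(tallies)
  expect_identical(tot$total_fail, 10)
  expect_identical(tot$total_pass, 153)
  expect_identical(tot$total_checks, 163)
  expect_equal(tot$total_score_display, 89.63)
  # summing the *rounded* rows would drift to 89.62
  rounded_rows <- mapply(score_dimension, tallies$fail, tallies$pass,
                         tallies$weight)
  expect_equal(sum(rounded_rows), 89.62)

  expect_equal(aggregate_report(
    data.frame(fail = 0, pass = 7, weight = 100))$total_score_display, 100)
  expect_error(aggregate_report(
    data.frame(fail = 0, pass = 1, weight = 60)), class = "oh_config_error")
})

test_that("aggregation equals an independent brute-force recomputation", {
  set.seed(99)
  for (i in 1:25) {
    tallies <- data.frame(fail = sample(0:20, 6, TRUE),
                          pass = sample(0:60, 6, TRUE))
    w <- c(50, 10, 10, 10, 10, 10)
    tallies$weight <- w
    tot <- aggregate_report(tallies)
    # naive recomputation, term by term
    expected <- 0
    for (j in 1:6) {
      n <- tallies$fail[j] + tallies$pass[j]
      expected <- expected + (if (n == 0) w[j] else w[j] * tallies$pass[j] / n)
    }
    expect_equal(tot$total_score, expected)
    expect_identical(tot$total_checks, sum(tallies$fail) + sum(tallies$pass))
  }
})

test_that("the engine agrees with the naive per-cell oracle on random cohorts", {
  schema <- demo_schema()
  for (seed in 1:5) {
    recs <- generate_cohort(schema, 15L, seed = seed)
    inj <- inject_errors(recs, c(minimal_req = 2, permissible = 2,
                                 range = 1, datatype = 1, mandatory_req = 3),
                         schema, seed = seed + 100L)
    rep <- run_qc(inj$records, compile_rules(schema))
    oracle <- brute_force_qc(inj$records, schema)
    got <- sort_findings(rep$findings[, c("patient_id", "variable",
                                          "rule_type", "outcome")])
    expect_identical(got, sort_findings(oracle))
  }
})

test_that("score bounds and monotonicity hold when defects are repaired", {
  schema <- demo_schema()
  recs <- generate_cohort(schema, 8L, seed = 21L)
  inj <- inject_errors(recs, c(permissible = 3, range = 1), schema,
                       seed = 5L)
  rules <- compile_rules(schema)
  rep <- run_qc(inj$records, rules)
  expect_true(rep$total_score > 0 && rep$total_score < 100)
  # repair one injected defect at a time: the score never decreases
  score <- rep$total_score
  fixed <- inj$records
  for (i in seq_len(nrow(inj$log$sites))) {
    site <- inj$log$sites[i, ]
    vdef <- schema$variables[[site$variable]]
    fixed[[site$row]]$cells[[site$variable]] <-
      recs[[site$row]]$cells[[site$variable]]
    s <- run_qc(fixed, rules)$total_score
    expect_gte(s, score)
    score <- s
  }
  expect_equal(score, 100)
})

test_that("weight configuration is validated and overridable", {
  expect_error(qc_weights(minimal_req = 40), class = "oh_config_error")
  expect_error(qc_weights(minimal_req = -10, mandatory_req = 110),
               class = "oh_config_error")
  w <- read_weights(oh_example("qc_weights.yaml"))
  expect_s3_class(w, "oh_weights")
  expect_identical(unname(w[["minimal_req"]]), 50)
  schema <- tiny_schema()
  recs <- list(record_from_raw(schema, list(biological_sex = "1")))
  expect_error(run_qc(recs, compile_rules(schema), weights = c(a = 1)),
               class = "oh_config_error")
  expect_error(run_qc(list(), compile_rules(schema)),
               class = "oh_config_error")
})

test_that("the rendered scorecard round-trips through its JSON form", {
  d <- scorecard_demo_cohort()
  rep <- run_qc(d$records, d$rules)
  path <- tempfile(fileext = ".json")
  write_qc_report(rep, path)
  back <- read_qc_report(path)
  expect_equal(back$tallies$fail, rep$tallies$fail)
  expect_equal(back$tallies$pass, rep$tallies$pass)
  expect_equal(back$tallies$score, rep$tallies$score_display)
  expect_equal(back$total$score, rep$total_score_display)
  expect_equal(back$total$checks, rep$total_checks)
  expect_identical(nrow(back$findings), nrow(rep$findings))

  txt <- render_report(rep, "text")
  expect_match(txt[1], "Dimension")
  expect_match(txt[length(txt)], "Total:")
  csv <- tempfile(fileext = ".csv")
  write_findings_csv(rep, csv)
  expect_identical(nrow(utils::read.csv(csv)), nrow(rep$findings))
})

test_that("per-patient ratings use the dimension weight budget", {
  schema <- demo_schema()
  recs <- generate_cohort(schema, 4L, seed = 9L)
  rep <- run_qc(recs, compile_rules(schema))
  ps <- rep$patient_scores
  # clean cohort: every patient at the full dimension weight
  expect_true(all(ps$score[ps$dimension == "Completeness"] == 60))
  expect_true(all(ps$score[ps$dimension == "Conformance"] == 30))
  expect_true(all(ps$score[ps$dimension == "Plausibility"] == 10))
})
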