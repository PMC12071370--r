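# Three-dimension quality assessment over parsed records.
#
# Dimensions and check types:
#   Completeness : minimal_req, mandatory_req  (required cell is present)
#   Conformance  : length, datatype, permissible
#   Plausibility : range
#
# Each executed (record, rule) pair yields exactly one pass/fail finding.
# Completeness rules always execute; conformance and plausibility rules are
# skipped on missing cells so a single blank is attributed once, to
# completeness, and never double-counted across dimensions. Datatype rules
# exist only for parse-constrained datatypes (integer, decimal, interval,
# boolean): a coded or free-text cell has no datatype restriction — its
# conformance is the permissible-value or length check.

RULE_TYPES <- c("minimal_req", "mandatory_req", "length", "datatype",
                "permissible", "range")
DIMENSION_OF <- c(
  minimal_req = "Completeness", mandatory_req = "Completeness",
  length = "Conformance", datatype = "Conformance",
  permissible = "Conformance", range = "Plausibility"
)
PARSE_CONSTRAINED <- c("integer", "decimal", "interval", "boolean")

#' Quality-check weight configuration
#'
#' One weight per check type, on a 0-100 budget that must sum to exactly 100.
#' The default puts half the weight on the minimal requirements (the ground
#' truth fields without which a record is unusable) and spreads the rest
#' evenly, but any split can be configured if a particular assessment is
#' deemed more important.
#'
#' @param minimal_req,mandatory_req,length,datatype,permissible,range
#'   non-negative weights summing to 100.
#' @return named numeric vector of class `oh_weights`.
#' @export
qc_weights <- function(minimal_req = 50, mandatory_req = 10, length = 10,
                       datatype = 10, permissible = 10, range = 10) {
  w <- c(minimal_req = minimal_req, mandatory_req = mandatory_req,
         length = length, datatype = datatype, permissible = permissible,
         range = range)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop_oh("weights must be non-negative numbers", "oh_config_error")
  }
  if (abs(sum(w) - 100) > 1e-9) {
    stop_oh(sprintf("weights must sum to 100 (got %s)", format(sum(w))),
            "oh_config_error")
  }
  structure(w, class = "oh_weights")
}

#' Read a weight configuration from a YAML file
#'
#' @param path YAML file with keys among the six check types.
#' @return an [qc_weights()] object.
#' @export
read_weights <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RULE_TYPES)
  if (length(unknown) > 0L) {
    stop_oh(sprintf("unknown weight keys: %s", paste(unknown,
                                                     collapse = ", ")),
            "oh_config_error")
  }
  do.call(qc_weights, lapply(cfg, as.numeric))
}

#' Compile the quality-control rule set for a schema
#'
#' For every non-identifier variable: one `minimal_req` rule iff its
#' requirement level is minimal; one `mandatory_req` rule iff minimal or
#' mandatory (a minimal variable is a fortiori mandatory); one `datatype`
#' rule iff the datatype is parse-constrained; one `permissible` rule iff
#' coded; one `length` rule iff a length cap is set; one `range` rule iff
#' range limits are set. The patient-identifier column is not scored —
#' missing or duplicated identifiers are fatal at ingestion.
#'
#' @param schema an `oh_schema`.
#' @return list of rules (rule_type, dimension, variable, schema_id, params).
#' @export
compile_rules <- function(schema) {
  stopifnot(inherits(schema, "oh_schema"))
  rules <- list()
  add <- function(rule_type, variable, params = list()) {
    rules[[length(rules) + 1L]] <<- structure(
      list(rule_type = rule_type,
           dimension = unname(DIMENSION_OF[[rule_type]]),
           variable = variable, schema_id = schema$schema_id,
           params = params),
      class = "oh_rule")
  }
  for (v in schema$variables) {
    if (identical(v$role, "identifier")) next
    if (identical(v$requirement_level, "minimal")) {
      add("minimal_req", v$name)
    }
    if (v$requirement_level %in% c("minimal", "mandatory")) {
      add("mandatory_req", v$name)
    }
    if (!is.null(v$max_length)) {
      add("length", v$name, list(max_length = v$max_length))
    }
    if (v$datatype %in% PARSE_CONSTRAINED) {
      add("datatype", v$name, list(datatype = v$datatype))
    }
    if (identical(v$datatype, "code")) {
      add("permissible", v$name,
          list(codes = vapply(v$value_set, `[[`, "", "internal_code")))
    }
    if (!is.null(v$range)) {
      add("range", v$name, list(min = v$range[1], max = v$range[2]))
    }
  }
  rules
}

# Evaluate one rule against one cell. Returns NULL when the check does not
# execute (missing or unparseable cell outside completeness), else a list
# (outcome, detail).
evaluate_rule <- function(rule, cell) {
  missing <- is.null(cell) || cell_is_missing(cell)
  if (rule$rule_type %in% c("minimal_req", "mandatory_req")) {
    return(if (missing) {
      list(outcome = "fail", detail = sprintf("required %s value is missing",
        sub("_req$", "", rule$rule_type)))
    } else {
      list(outcome = "pass", detail = "value present")
    })
  }
  if (missing) return(NULL)
  switch(rule$rule_type,
    length = {
      if (nchar(cell$raw) > rule$params$max_length) {
        list(outcome = "fail",
             detail = sprintf("length %d exceeds cap %d", nchar(cell$raw),
                              as.integer(rule$params$max_length)))
      } else list(outcome = "pass", detail = "within length cap")
    },
    datatype = {
      if (is.null(cell$parsed)) {
        list(outcome = "fail",
             detail = sprintf("'%s' is not a valid %s", cell$raw,
                              rule$params$datatype))
      } else list(outcome = "pass", detail = "datatype conforms")
    },
    permissible = {
      if (cell$raw %in% rule$params$codes) {
        list(outcome = "pass", detail = "code in value set")
      } else {
        list(outcome = "fail",
             detail = sprintf("code '%s' not in value set", cell$raw))
      }
    },
    range = {
      if (is.null(cell$parsed) || !is.numeric(cell$parsed)) {
        NULL  # unparseable: already a datatype failure, not implausibility
      } else if (cell$parsed < rule$params$min ||
                 cell$parsed > rule$params$max) {
        list(outcome = "fail",
             detail = sprintf("%s outside [%s, %s]", format(cell$parsed),
                              format(rule$params$min),
                              format(rule$params$max)))
      } else list(outcome = "pass", detail = "within range")
    }
  )
}

#' Score one quality dimension row
#'
#' `weight * pass / (fail + pass)` on the 0-100 scale, rounded half-up to two
#' decimals for display. A check type that executed zero checks keeps its
#' full weight: an absent defect class is vacuously satisfied and must never
#' penalize the score.
#'
#' @param fail,pass non-negative counts.
#' @param weight non-negative weight.
#' @return the rounded score.
#' @export
#' @examples
#' score_dimension(2, 16, 50)  # 44.44
score_dimension <- function(fail, pass, weight) {
  stopifnot(fail >= 0, pass >= 0, weight >= 0)
  round_half_up(score_dimension_raw(fail, pass, weight), 2)
}

score_dimension_raw <- function(fail, pass, weight) {
  total <- fail + pass
  if (total == 0) weight else weight * pass / total
}

#' Aggregate dimension tallies into report totals
#'
#' Sums the unrounded weighted row scores and rounds the sum once for
#' display; rounding each row first and summing would drift (the rounded
#' rows of the reference report sum to 89.62 against a true 89.63).
#'
#' @param tallies data.frame with columns fail, pass, weight (one row per
#'   check type).
#' @return list with total_fail, total_pass, total_checks, total_score
#'   (unrounded) and total_score_display (2-decimal half-up).
#' @export
aggregate_report <- function(tallies) {
  stopifnot(is.data.frame(tallies),
            all(c("fail", "pass", "weight") %in% names(tallies)))
  if (abs(sum(tallies$weight) - 100) > 1e-9) {
    stop_oh(sprintf("weights must sum to 100 (got %s)",
                    format(sum(tallies$weight))), "oh_config_error")
  }
  raw <- sum(mapply(score_dimension_raw, tallies$fail, tallies$pass,
                    tallies$weight))
  list(
    total_fail = sum(tallies$fail),
    total_pass = sum(tallies$pass),
    total_checks = sum(tallies$fail + tallies$pass),
    total_score = raw,
    total_score_display = round_half_up(raw, 2)
  )
}

#' Run the quality assessment
#'
#' Executes every applicable (record, rule) pair; a rule applies to a record
#' when their schema identifiers match, so a pooled multi-schema cohort can
#' be scored against the concatenated rule sets of its schemas.
#'
#' @param records list of `oh_record` (non-empty).
#' @param rules rule list from [compile_rules()] (concatenate for pooled
#'   cohorts).
#' @param weights an [qc_weights()] configuration.
#' @return object of class `oh_qc_report`: tallies (one row per check type),
#'   findings, totals, per-patient dimension scores.
#' @export
run_qc <- function(records, rules, weights = qc_weights()) {
  if (length(records) == 0L) {
    stop_oh("no records to assess", "oh_config_error")
  }
  if (!inherits(weights, "oh_weights")) {
    stop_oh("weights must be built with qc_weights() or read_weights()",
            "oh_config_error")
  }
  pid <- character(); var <- character(); rty <- character()
  dim_ <- character(); out <- character(); det <- character()
  for (rec in records) {
    for (rule in rules) {
      if (!identical(rule$schema_id, rec$schema_id)) next
      res <- evaluate_rule(rule, rec$cells[[rule$variable]])
      if (is.null(res)) next
      k <- length(pid) + 1L
      pid[k] <- rec$patient_id; var[k] <- rule$variable
      rty[k] <- rule$rule_type; dim_[k] <- rule$dimension
      out[k] <- res$outcome; det[k] <- res$detail
    }
  }
  findings <- data.frame(patient_id = pid, variable = var, rule_type = rty,
                         dimension = dim_, outcome = out, detail = det,
                         stringsAsFactors = FALSE)
  tallies <- data.frame(
    dimension = unname(DIMENSION_OF[RULE_TYPES]),
    rule_type = RULE_TYPES,
    fail = vapply(RULE_TYPES, function(t)
      sum(findings$rule_type == t & findings$outcome == "fail"), 0),
    pass = vapply(RULE_TYPES, function(t)
      sum(findings$rule_type == t & findings$outcome == "pass"), 0),
    weight = as.numeric(weights[RULE_TYPES]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tallies$total <- tallies$fail + tallies$pass
  tallies$score <- mapply(score_dimension_raw, tallies$fail, tallies$pass,
                          tallies$weight)
  tallies$score_display <- round_half_up(tallies$score, 2)
  totals <- aggregate_report(tallies)

  # Per-patient rating: pass fraction per dimension, weighted by the
  # dimension's share of the weight budget (the same formula as the cohort
  # rows, applied within one patient).
  dim_weight <- tapply(tallies$weight, tallies$dimension, sum)
  ps <- do.call(rbind, lapply(unique(findings$patient_id), function(p) {
    f <- findings[findings$patient_id == p, ]
    do.call(rbind, lapply(names(dim_weight), function(d) {
      fd <- f[f$dimension == d, ]
      data.frame(
        patient_id = p, dimension = d, checks = nrow(fd),
        passed = sum(fd$outcome == "pass"),
        score = round_half_up(score_dimension_raw(
          sum(fd$outcome == "fail"), sum(fd$outcome == "pass"),
          dim_weight[[d]]), 2),
        stringsAsFactors = FALSE)
    }))
  }))
  structure(
    list(tallies = tallies, findings = findings,
         total_fail = totals$total_fail, total_pass = totals$total_pass,
         total_checks = totals$total_checks,
         total_score = totals$total_score,
         total_score_display = totals$total_score_display,
         patient_scores = ps),
    class = "oh_qc_report"
  )
}

#' @export
print.oh_qc_report <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Render a quality report as a scorecard
#'
#' The text form reproduces the standard scorecard layout (Dimension, Type,
#' Fail, Pass, Total, Weight, Score, and a totals row); scores always print
#' with exactly two decimals. The JSON form is machine-readable and
#' round-trips through [read_qc_report()].
#'
#' @param report an `oh_qc_report`.
#' @param format `"text"` or `"json"`.
#' @return character vector of lines (`"text"`) or a JSON string (`"json"`).
#' @export
render_report <- function(report, format = c("text", "json")) {
  format <- match.arg(format)
  t <- report$tallies
  if (format == "json") {
    doc <- list(
      tallies = data.frame(
        dimension = t$dimension, rule_type = t$rule_type, fail = t$fail,
        pass = t$pass, total = t$total, weight = t$weight,
        score = t$score_display, stringsAsFactors = FALSE),
      total = list(fail = report$total_fail, pass = report$total_pass,
                   checks = report$total_checks, weight = sum(t$weight),
                   score = report$total_score_display),
      findings = report$findings,
      patient_scores = report$patient_scores
    )
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2))
  }
  fmt <- "%-14s %-14s %6s %6s %6s %7s %8s"
  lines <- c(
    sprintf(fmt, "Dimension", "Type", "Fail", "Pass", "Total", "Weight",
            "Score"),
    sprintf(fmt, t$dimension, t$rule_type, t$fail, t$pass, t$total,
            format(t$weight, trim = TRUE),
            paste0(sprintf("%.2f", t$score_display), "%")),
    sprintf(fmt, "Total:", "", report$total_fail, report$total_pass,
            report$total_checks, format(sum(t$weight), trim = TRUE),
            paste0(sprintf("%.2f", report$total_score_display), "%"))
  )
  lines
}

#' Write / read the machine-readable scorecard
#'
#' @param report an `oh_qc_report`.
#' @param path file path.
#' @return `path` invisibly; [read_qc_report()] returns the parsed report
#'   (tallies and totals identical to the source report).
#' @export
write_qc_report <- function(report, path) {
  writeLines(render_report(report, format = "json"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_qc_report
#' @export
read_qc_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  doc
}

#' Export findings as CSV
#'
#' @param report an `oh_qc_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_findings_csv <- function(report, path) {
  utils::write.csv(report$findings[, c("patient_id", "variable", "rule_type",
                                       "outcome", "detail")],
                   path, row.names = FALSE)
  invisible(path)
}
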