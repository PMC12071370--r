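# Schema-conformant synthetic cohorts with bookkept fault injection.
#
# The generator emulates a harmonized row-per-patient oncology table: coded
# cells drawn uniformly from the variable's value set, numeric cells within
# declared ranges (or a 0-100 default), intervals within plausible follow-up
# bounds (0-60 units), hashed patient identifiers. It does not model
# clinically realistic joint distributions — cells are independent — so
# passing tests demonstrate pipeline correctness, not clinical realism.

DEMO_SITE_SALT <- "demo-site-salt"
DEMO_PLATFORM_SALT <- "demo-platform-salt"

random_string <- function(n_chars) {
  paste(sample(letters, n_chars, replace = TRUE), collapse = "")
}

generate_cell_raw <- function(vdef) {
  switch(vdef$datatype,
    code = sample(vapply(vdef$value_set, `[[`, "", "internal_code"), 1L),
    integer = {
      lo <- if (!is.null(vdef$range)) ceiling(vdef$range[1]) else 0
      hi <- if (!is.null(vdef$range)) floor(vdef$range[2]) else 100
      sprintf("%d", as.integer(sample(seq(lo, hi), 1L)))
    },
    decimal = {
      lo <- if (!is.null(vdef$range)) vdef$range[1] else 0
      hi <- if (!is.null(vdef$range)) vdef$range[2] else 100
      sprintf("%.2f", stats::runif(1L, lo, hi))
    },
    boolean = sample(c("0", "1"), 1L),
    interval = sprintf("%d %s", sample(0:60, 1L),
                       sample(INTERVAL_UNITS, 1L)),
    string = random_string(min(8L, as.integer(vdef$max_length %||% 8L)))
  )
}

#' Generate a schema-conformant synthetic cohort
#'
#' Every generated record is fully compliant by construction: a
#' zero-injection cohort always scores 100.00% under [run_qc()]. Patient
#' identifiers are double-hashed demo identifiers. Deterministic under
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param schema an `oh_schema`.
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @return list of `oh_record` with an `emission_log` attribute
#'   (data.frame variable/non_missing bookkeeping).
#' @export
generate_cohort <- function(schema, n, seed = 1L) {
  stopifnot(inherits(schema, "oh_schema"), n >= 1L)
  id_var <- identifier_variable(schema)
  with_seed(seed, {
    records <- lapply(seq_len(n), function(i) {
      pid <- hash_patient_id(sprintf("%s-P%04d", schema$schema_id, i),
                             DEMO_SITE_SALT, DEMO_PLATFORM_SALT)
      cells <- list()
      for (v in schema$variables) {
        raw <- if (identical(v$role, "identifier")) pid else
          generate_cell_raw(v)
        cells[[v$name]] <- parse_cell(raw, v)
      }
      new_record(pid, schema$schema_id, cells)
    })
    non_id <- setdiff(schema_variable_names(schema), id_var)
    attr(records, "emission_log") <- data.frame(
      variable = non_id,
      non_missing = vapply(non_id, function(var)
        sum(vapply(records, function(r)
          !cell_is_missing(r$cells[[var]]), TRUE)), 0L),
      row.names = NULL, stringsAsFactors = FALSE)
    records
  })
}

# Cells eligible to receive a defect of each type, as (record index,
# variable) pairs. Mirrors the QC rule applicability so injected defects are
# recovered exactly by the engine.
eligible_sites <- function(records, schemas, rule_type, variables = NULL) {
  sites <- list()
  for (i in seq_along(records)) {
    schema <- schemas[[records[[i]]$schema_id]]
    for (v in schema$variables) {
      if (identical(v$role, "identifier")) next
      if (!is.null(variables) && !v$name %in% variables) next
      ok <- switch(rule_type,
        minimal_req = identical(v$requirement_level, "minimal"),
        mandatory_req = identical(v$requirement_level, "mandatory"),
        length = !is.null(v$max_length),
        datatype = v$datatype %in% PARSE_CONSTRAINED && is.null(v$range),
        permissible = identical(v$datatype, "code"),
        range = !is.null(v$range)
      )
      if (ok) sites[[length(sites) + 1L]] <- list(record = i, variable = v)
    }
  }
  sites
}

corrupt_cell <- function(vdef, cell, rule_type) {
  raw <- switch(rule_type,
    minimal_req = ,
    mandatory_req = "",
    datatype = "not_a_number",
    permissible = {
      bad <- "UNLISTED_CODE"
      codes <- vapply(vdef$value_set, `[[`, "", "internal_code")
      while (bad %in% codes) bad <- paste0(bad, "X")
      bad
    },
    length = strrep("x", as.integer(vdef$max_length) + 5L),
    range = {
      # out of range by at least one unit
      hi <- vdef$range[2] + 1
      if (identical(vdef$datatype, "integer")) sprintf("%d", as.integer(hi))
      else sprintf("%.2f", hi)
    }
  )
  parse_cell(raw, vdef)
}

#' Inject bookkept rule violations into a cohort
#'
#' Requested counts are target per-type QC *fail* counts. Defect
#' realizations: completeness types blank the cell; `datatype` plants a
#' non-numeric token; `permissible` a code outside the value set; `length`
#' an overlong string; `range` a value outside the limits by at least one
#' unit. Sites never overlap, and each defect perturbs exactly one check
#' type — in particular, blanking a minimal cell also fails the mandatory
#' requirement (a minimal variable is a fortiori mandatory), so when both
#' completeness counts are requested the engine blanks
#' `mandatory_req - minimal_req` cells of purely-mandatory variables and
#' rejects `mandatory_req < minimal_req` as infeasible.
#'
#' @param records cohort from [generate_cohort()] (or a pooled list).
#' @param spec named numeric vector of target fail counts per rule type,
#'   e.g. `c(minimal_req = 2, permissible = 3)`; or a named list whose
#'   entries are either counts or `list(count =, variables =)` to restrict
#'   eligible variables.
#' @param schemas one `oh_schema`, or a list of schemas for pooled cohorts.
#' @param seed integer seed for site selection.
#' @return `list(records, log)` where `log` is an `oh_injection_log`:
#'   data.frame of defect sites plus per-type counts.
#' @export
inject_errors <- function(records, spec, schemas, seed = 1L) {
  if (inherits(schemas, "oh_schema")) schemas <- list(schemas)
  names(schemas) <- vapply(schemas, `[[`, "", "schema_id")
  if (is.numeric(spec)) spec <- as.list(spec)
  unknown <- setdiff(names(spec), RULE_TYPES)
  if (length(unknown) > 0L) {
    stop_oh(sprintf("unknown rule types in injection spec: %s",
                    paste(unknown, collapse = ", ")), "oh_config_error")
  }
  counts <- vapply(spec, function(s)
    if (is.list(s)) as.numeric(s$count) else as.numeric(s), 0)
  restrict <- lapply(spec, function(s) if (is.list(s)) s$variables)

  # completeness coupling: minimal blanks already fail mandatory_req
  plan <- counts
  if (!is.null(spec$mandatory_req) && !is.null(spec$minimal_req)) {
    extra <- counts[["mandatory_req"]] - counts[["minimal_req"]]
    if (extra < 0) {
      stop_oh(paste("infeasible spec: mandatory_req fails cannot be fewer",
                    "than minimal_req fails (minimal blanks fail both)"),
              "oh_config_error")
    }
    plan[["mandatory_req"]] <- extra
  }

  used <- character()
  log <- data.frame(rule_type = character(), patient_id = character(),
                    variable = character(), row = integer(),
                    stringsAsFactors = FALSE)
  with_seed(seed, {
    for (rule_type in intersect(RULE_TYPES, names(plan))) {
      k <- plan[[rule_type]]
      if (k == 0) next
      sites <- eligible_sites(records, schemas, rule_type,
                              restrict[[rule_type]])
      keys <- vapply(sites, function(s) paste(s$record, s$variable$name,
                                              sep = "\r"), "")
      open <- which(!keys %in% used)
      if (length(open) < k) {
        stop_oh(sprintf(
          "infeasible injection: %d %s defects requested, %d eligible cells",
          k, rule_type, length(open)), "oh_config_error")
      }
      pick <- open[sample.int(length(open), k)]
      for (j in pick) {
        s <- sites[[j]]
        rec <- records[[s$record]]
        rec$cells[[s$variable$name]] <- corrupt_cell(
          s$variable, rec$cells[[s$variable$name]], rule_type)
        records[[s$record]] <- rec
        used <- c(used, keys[j])
        log <- rbind(log, data.frame(
          rule_type = rule_type, patient_id = rec$patient_id,
          variable = s$variable$name, row = s$record,
          stringsAsFactors = FALSE))
      }
    }
  })
  counts_out <- vapply(RULE_TYPES, function(t)
    sum(log$rule_type == t), 0L)
  # record the *target fail counts* (minimal blanks count toward mandatory)
  if ("minimal_req" %in% log$rule_type) {
    counts_out[["mandatory_req"]] <- counts_out[["mandatory_req"]] +
      counts_out[["minimal_req"]]
  }
  structure(list(records = records,
                 log = structure(list(sites = log, counts = counts_out),
                                 class = "oh_injection_log")),
            class = "oh_injection_result")
}

#' @export
print.oh_injection_log <- function(x, ...) {
  cat("injected defects:\n")
  for (t in names(x$counts)) {
    if (x$counts[[t]] > 0) cat(sprintf("  %-14s %d\n", t, x$counts[[t]]))
  }
  invisible(x)
}

#' Write an injection log as a machine-readable sidecar file
#'
#' @param log an `oh_injection_log`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_injection_log <- function(log, path) {
  writeLines(jsonlite::toJSON(list(counts = as.list(log$counts),
                                   sites = log$sites),
                              auto_unbox = TRUE, digits = NA, pretty = 2),
             path, useBytes = TRUE)
  invisible(path)
}
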