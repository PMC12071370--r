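# The machine-readable data dictionary: one document per data schema, binding
# every study variable to its datatype, requirement tier, value set with
# ontology codes, and target FHIR R4B element. The dictionary drives both the
# quality-control rule set and the FHIR transform, so it is the single source
# of truth for a schema.

REQUIREMENT_LEVELS <- c("minimal", "mandatory", "recommended")
DATATYPES <- c("code", "integer", "decimal", "string", "interval", "boolean")

#' Construct a value-set entry
#'
#' Binds one raw capture-form code (the REDCap internal codification) to its
#' label and ontology coding. A sentinel entry marks the grouped category
#' "other"; its coding is typically a SNOMED post-coordinated expression
#' giving the grouped concept explicit semantics.
#'
#' @param internal_code raw code as it appears in capture-form exports.
#' @param label human-readable label.
#' @param coding an [coding()] object.
#' @param sentinel logical; TRUE for the grouped "other" entry.
#' @return object of class `oh_value_set_entry`.
#' @export
value_set_entry <- function(internal_code, label, coding, sentinel = FALSE) {
  stopifnot(is_string(internal_code), nzchar(internal_code), is_string(label),
            inherits(coding, "oh_coding"), is.logical(sentinel))
  structure(
    list(internal_code = internal_code, label = label, coding = coding,
         sentinel = isTRUE(sentinel)),
    class = "oh_value_set_entry"
  )
}

#' Construct a variable definition
#'
#' One dictionary entry. Constructors perform only light shape checks so that
#' deliberately broken definitions can be fed to [validate_dictionary()];
#' [load_dictionary()] refuses any schema the validator flags.
#'
#' @param name variable name (unique within its schema).
#' @param schema_id identifier of the owning schema.
#' @param requirement_level one of `"minimal"`, `"mandatory"`, `"recommended"`.
#' @param datatype one of `"code"`, `"integer"`, `"decimal"`, `"string"`,
#'   `"interval"`, `"boolean"`.
#' @param resource_kind target FHIR resource kind.
#' @param element_path dot-separated FHIR element path incl. kind prefix.
#' @param value_set list of [value_set_entry()] (required iff datatype "code").
#' @param max_length optional positive integer length cap.
#' @param range optional numeric `c(min, max)` plausibility limits.
#' @param unit optional unit string for quantity-bearing elements.
#' @param resource_group grouping key: variables of one kind sharing a group
#'   populate the same resource instance. Defaults to the variable name.
#' @param fixed_codings optional named list `path -> coding()` of fixed
#'   codings stamped on the variable's resource (e.g. `Observation.code`).
#' @param role `"data"` or `"identifier"` (the hashed patient-ID column).
#' @return object of class `oh_variable`.
#' @export
variable_definition <- function(name, schema_id, requirement_level, datatype,
                                resource_kind, element_path,
                                value_set = NULL, max_length = NULL,
                                range = NULL, unit = NULL,
                                resource_group = NULL, fixed_codings = NULL,
                                role = "data") {
  stopifnot(is_string(name), nzchar(name), is_string(schema_id))
  structure(
    list(
      name = name, schema_id = schema_id,
      requirement_level = requirement_level, datatype = datatype,
      resource_kind = resource_kind, element_path = element_path,
      value_set = value_set, max_length = max_length, range = range,
      unit = unit, resource_group = resource_group %||% name,
      fixed_codings = fixed_codings, role = match.arg(role,
                                                      c("data", "identifier"))
    ),
    class = "oh_variable"
  )
}

#' Construct a schema definition
#'
#' @param schema_id schema identifier.
#' @param variables ordered list of [variable_definition()] objects.
#' @param use_cases character vector of use-case labels served by the schema.
#' @return object of class `oh_schema`.
#' @export
schema_definition <- function(schema_id, variables, use_cases = character()) {
  stopifnot(is_string(schema_id), is.list(variables))
  names(variables) <- vapply(variables, function(v) v$name %||% "", "")
  structure(
    list(schema_id = schema_id, use_cases = use_cases, variables = variables),
    class = "oh_schema"
  )
}

#' @export
print.oh_schema <- function(x, ...) {
  cat(sprintf("<data schema '%s'>: %d variables", x$schema_id,
              length(x$variables)), "\n")
  for (v in x$variables) {
    cat(sprintf("  %-24s %-10s %-11s -> %s\n", v$name, v$datatype,
                v$requirement_level, v$element_path))
  }
  invisible(x)
}

identifier_variable <- function(schema) {
  roles <- vapply(schema$variables, function(v) identical(v$role,
                                                          "identifier"), TRUE)
  names(schema$variables)[roles]
}

schema_variable_names <- function(schema) {
  names(schema$variables)
}

#' Validate a schema against the dictionary invariants
#'
#' Violations are returned as data, not raised: each string names the
#' offending variable and the rule it breaks, so a dictionary author sees
#' every problem at once.
#'
#' @param schema an `oh_schema`.
#' @return character vector of violation descriptions (empty when valid).
#' @export
validate_dictionary <- function(schema) {
  violations <- character()
  add <- function(...) violations <<- c(violations, sprintf(...))

  if (!inherits(schema, "oh_schema")) {
    return("not a schema definition object")
  }
  nm <- vapply(schema$variables, function(v) v$name %||% "", "")
  dup <- unique(nm[duplicated(nm)])
  for (d in dup) add("variable '%s': name is not unique within the schema", d)
  ids <- identifier_variable(schema)
  if (length(ids) == 0L) add("schema '%s': no patient-identifier variable",
                             schema$schema_id)
  if (length(ids) > 1L) add("schema '%s': multiple identifier variables (%s)",
                            schema$schema_id, paste(ids, collapse = ", "))

  for (v in schema$variables) {
    if (!is_string(v$requirement_level) ||
        !v$requirement_level %in% REQUIREMENT_LEVELS) {
      add("variable '%s': requirement_level must be one of %s", v$name,
          paste(REQUIREMENT_LEVELS, collapse = "/"))
    }
    if (!is_string(v$datatype) || !v$datatype %in% DATATYPES) {
      add("variable '%s': unknown datatype '%s'", v$name,
          as.character(v$datatype %||% NA))
      next
    }
    if (v$datatype == "code") {
      if (length(v$value_set) == 0L) {
        add("variable '%s': coded variable lacks a value set", v$name)
      } else {
        codes <- vapply(v$value_set, `[[`, "", "internal_code")
        for (d in unique(codes[duplicated(codes)])) {
          add("variable '%s': duplicate internal code '%s' in value set",
              v$name, d)
        }
      }
    } else if (length(v$value_set) > 0L) {
      add("variable '%s': value set given for non-coded datatype '%s'",
          v$name, v$datatype)
    }
    if (!is.null(v$range)) {
      if (!v$datatype %in% c("integer", "decimal")) {
        add("variable '%s': range limits only apply to numeric datatypes",
            v$name)
      } else if (length(v$range) != 2L || !is.numeric(v$range) ||
                 anyNA(v$range)) {
        add("variable '%s': range must be a numeric [min, max] pair", v$name)
      } else if (v$range[1] > v$range[2]) {
        add("variable '%s': range minimum %s exceeds maximum %s", v$name,
            format(v$range[1]), format(v$range[2]))
      }
    }
    if (!is.null(v$max_length) &&
        (!is.numeric(v$max_length) || length(v$max_length) != 1L ||
         v$max_length < 1 || v$max_length != floor(v$max_length))) {
      add("variable '%s': max_length must be a positive integer", v$name)
    }
    chk <- check_element_path(v$resource_kind %||% "", v$element_path %||% "",
                              v$datatype)
    if (!isTRUE(chk)) add("variable '%s': %s", v$name, chk)
    if (!is.null(v$fixed_codings)) {
      for (p in names(v$fixed_codings)) {
        if (!p %in% FIXED_CODING_PATHS) {
          add("variable '%s': fixed coding path '%s' is not supported",
              v$name, p)
        }
        if (!inherits(v$fixed_codings[[p]], "oh_coding")) {
          add("variable '%s': fixed coding at '%s' is not a coding object",
              v$name, p)
        }
      }
    }
  }
  violations
}

#' Resolve a raw internal code to its ontology coding
#'
#' Lookup is total over the variable's value set: an unknown raw code raises
#' an unmapped-value error carrying the variable name and the offending code
#' (the transform stage is strict even though ingestion is lenient).
#'
#' @param vdef a coded [variable_definition()].
#' @param internal_code raw code string.
#' @return the bound [coding()].
#' @export
resolve_code <- function(vdef, internal_code) {
  stopifnot(inherits(vdef, "oh_variable"))
  if (!identical(vdef$datatype, "code")) {
    stop_oh(sprintf("variable '%s' is not a coded variable", vdef$name),
            "oh_unmapped_value_error")
  }
  for (entry in vdef$value_set) {
    if (identical(entry$internal_code, internal_code)) return(entry$coding)
  }
  stop_oh(
    sprintf("variable '%s': raw code '%s' is not in the value set",
            vdef$name, internal_code),
    "oh_unmapped_value_error",
    variable = vdef$name, code = internal_code
  )
}

# ---- dictionary files (YAML, one document per schema) -----------------------

coding_from_config <- function(x, where) {
  for (k in c("system", "code")) {
    if (is.null(x[[k]])) {
      stop_oh(sprintf("%s: missing key '%s'", where, k), "oh_format_error")
    }
  }
  coding(x$system, as.character(x$code), x$display)
}

variable_from_config <- function(x, schema_id, idx) {
  where <- sprintf("variable %d ('%s')", idx, x$name %||% "?")
  for (k in c("name", "requirement_level", "datatype", "resource_kind",
              "element_path")) {
    if (is.null(x[[k]])) {
      stop_oh(sprintf("%s: missing key '%s'", where, k), "oh_format_error")
    }
  }
  vs <- NULL
  if (!is.null(x$value_set)) {
    vs <- lapply(seq_along(x$value_set), function(i) {
      e <- x$value_set[[i]]
      w <- sprintf("%s, value-set entry %d", where, i)
      if (is.null(e$internal_code) || is.null(e$label)) {
        stop_oh(sprintf("%s: needs internal_code and label", w),
                "oh_format_error")
      }
      value_set_entry(as.character(e$internal_code), e$label,
                      coding_from_config(e, w), isTRUE(e$sentinel))
    })
  }
  fixed <- NULL
  if (!is.null(x$fixed_codings)) {
    fixed <- lapply(x$fixed_codings, coding_from_config,
                    where = paste(where, "fixed coding"))
    names(fixed) <- vapply(x$fixed_codings,
                           function(e) e$path %||%
                             stop_oh(sprintf("%s: fixed coding without path",
                                             where), "oh_format_error"), "")
  }
  variable_definition(
    name = x$name, schema_id = schema_id,
    requirement_level = x$requirement_level, datatype = x$datatype,
    resource_kind = x$resource_kind, element_path = x$element_path,
    value_set = vs,
    max_length = if (!is.null(x$max_length)) as.numeric(x$max_length),
    range = if (!is.null(x$range)) as.numeric(unlist(x$range)),
    unit = x$unit, resource_group = x$resource_group,
    fixed_codings = fixed,
    role = x$role %||% "data"
  )
}

#' Load a data dictionary from a YAML config file
#'
#' Parses one schema document and refuses it unless every dictionary
#' invariant holds; all violations are reported together. Variable order in
#' the file is preserved (it fixes CSV column order and resource build order).
#'
#' @param path path to a dictionary YAML file.
#' @return a validated `oh_schema`.
#' @export
#' @examples
#' schema <- load_dictionary(oh_example("breast_demo.yaml"))
#' length(schema$variables)
load_dictionary <- function(path) {
  if (!file.exists(path)) {
    stop_oh(sprintf("dictionary file not found: %s", path), "oh_format_error")
  }
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_oh(
      sprintf("cannot parse dictionary '%s': %s", path, conditionMessage(e)),
      "oh_format_error")
  )
  if (is.null(doc$schema_id)) {
    stop_oh("dictionary is missing top-level key 'schema_id'",
            "oh_format_error")
  }
  if (is.null(doc$variables) || length(doc$variables) == 0L) {
    stop_oh("dictionary declares no variables", "oh_format_error")
  }
  vars <- lapply(seq_along(doc$variables), function(i) {
    variable_from_config(doc$variables[[i]], doc$schema_id, i)
  })
  schema <- schema_definition(doc$schema_id, vars,
                              use_cases = as.character(doc$use_cases %||%
                                                         character()))
  violations <- validate_dictionary(schema)
  if (length(violations) > 0L) {
    stop_oh(paste0("dictionary validation failed:\n",
                   paste0("  - ", violations, collapse = "\n")),
            "oh_dictionary_error", violations = violations)
  }
  schema
}

#' Serialize a schema back to the dictionary YAML format
#'
#' Inverse of [load_dictionary()]: loading the written file reproduces the
#' schema (round-trip identity).
#'
#' @param schema an `oh_schema`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
serialize_dictionary <- function(schema, path) {
  stopifnot(inherits(schema, "oh_schema"))
  drop_null <- function(x) x[!vapply(x, is.null, TRUE)]
  vars <- lapply(schema$variables, function(v) {
    out <- list(
      name = v$name,
      role = if (identical(v$role, "identifier")) "identifier",
      requirement_level = v$requirement_level,
      datatype = v$datatype,
      resource_kind = v$resource_kind,
      element_path = v$element_path,
      resource_group = if (!identical(v$resource_group, v$name))
        v$resource_group,
      max_length = v$max_length,
      range = if (!is.null(v$range)) as.list(v$range),
      unit = v$unit,
      value_set = if (length(v$value_set) > 0L) lapply(v$value_set, function(e)
        drop_null(list(
          internal_code = e$internal_code, label = e$label,
          system = e$coding$system, code = e$coding$code,
          display = e$coding$display,
          sentinel = if (e$sentinel) TRUE))),
      fixed_codings = if (length(v$fixed_codings) > 0L)
        lapply(names(v$fixed_codings), function(p) drop_null(list(
          path = p, system = v$fixed_codings[[p]]$system,
          code = v$fixed_codings[[p]]$code,
          display = v$fixed_codings[[p]]$display)))
    )
    drop_null(out)
  })
  doc <- drop_null(list(
    schema_id = schema$schema_id,
    use_cases = if (length(schema$use_cases) > 0L)
      as.list(schema$use_cases),
    variables = unname(vars)
  ))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Path to a packaged example file
#'
#' @param file file name under the package's `extdata/` (listed when empty).
#' @return full path, or a listing of available files.
#' @export
oh_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "oncoharmonizer")))
  }
  path <- system.file("extdata", file, package = "oncoharmonizer")
  if (!nzchar(path)) stop_oh(sprintf("no packaged example '%s'", file),
                             "oh_format_error")
  path
}
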