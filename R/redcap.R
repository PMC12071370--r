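# REDCap-export-dialect CSV interchange: one row per patient, raw internal
# codes for categorical fields, empty string as the sole missing marker.
# Ingestion is deliberately lenient: an unparseable cell keeps its raw text
# and surfaces later as a datatype-conformance failure, never as a crash.

#' Parse one raw cell under its governing variable definition
#'
#' @param raw cell text as read from the file.
#' @param vdef the governing [variable_definition()].
#' @return an `oh_cell`: list(raw, parsed, note). `parsed` is NULL for the
#'   missing marker ("" on disk) and for unparseable text (with a note).
#' @export
parse_cell <- function(raw, vdef) {
  raw <- as.character(raw %||% "")
  if (is.na(raw)) raw <- ""
  cell <- list(raw = raw, parsed = NULL, note = NULL)
  if (!nzchar(raw)) {
    return(structure(cell, class = "oh_cell"))
  }
  parsed <- switch(vdef$datatype,
    code = raw,
    string = raw,
    integer = if (grepl("^[+-]?[0-9]+$", raw)) as.numeric(raw),
    decimal = if (grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)$", raw))
      as.numeric(raw),
    boolean = if (tolower(raw) %in% c("0", "1", "true", "false"))
      tolower(raw) %in% c("1", "true"),
    interval = if (grepl("^[0-9]+ (days|weeks|months)$", raw)) {
      parts <- strsplit(raw, " ", fixed = TRUE)[[1L]]
      time_interval(as.numeric(parts[1L]), parts[2L])
    }
  )
  if (is.null(parsed)) {
    cell$note <- sprintf("'%s' is not a valid %s", raw, vdef$datatype)
  } else {
    cell$parsed <- parsed
  }
  structure(cell, class = "oh_cell")
}

cell_is_missing <- function(cell) !nzchar(cell$raw)

format_cell <- function(cell) cell$raw

new_record <- function(patient_id, schema_id, cells) {
  structure(
    list(patient_id = patient_id, schema_id = schema_id, cells = cells),
    class = "oh_record"
  )
}

#' @export
print.oh_record <- function(x, ...) {
  cat(sprintf("<patient record %s> schema '%s', %d cells (%d non-missing)\n",
              substr(x$patient_id, 1L, 12L), x$schema_id, length(x$cells),
              sum(!vapply(x$cells, cell_is_missing, TRUE))))
  invisible(x)
}

#' Parse a REDCap-style CSV export into patient records
#'
#' Dialect: comma-delimited, double-quote quoting, UTF-8, first row header,
#' empty string as the only missing marker. Cells that fail to parse under
#' their declared datatype are retained with their raw text plus a parse
#' note (available as `attr(records, "parse_notes")`); they fail datatype
#' conformance during QC instead of aborting ingestion. A missing identifier
#' column or duplicated patient IDs are fatal.
#'
#' @param path CSV file path.
#' @param schema the governing `oh_schema`.
#' @return list of `oh_record` in file order, with a `parse_notes` attribute
#'   (data.frame row/column/raw/note).
#' @export
parse_export <- function(path, schema) {
  stopifnot(inherits(schema, "oh_schema"))
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(), fileEncoding = "UTF-8")
  id_var <- identifier_variable(schema)
  if (!id_var %in% names(tab)) {
    stop_oh(sprintf("identifier column '%s' is missing from %s", id_var,
                    path), "oh_format_error")
  }
  known <- intersect(names(tab), schema_variable_names(schema))
  notes <- list()
  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cells <- list()
    for (var in known) {
      vdef <- schema$variables[[var]]
      cell <- parse_cell(tab[i, var], vdef)
      if (!is.null(cell$note)) {
        notes[[length(notes) + 1L]] <- data.frame(
          row = i, column = var, raw = cell$raw, note = cell$note,
          stringsAsFactors = FALSE)
      }
      cells[[var]] <- cell
    }
    pid <- tab[i, id_var]
    if (!nzchar(pid)) {
      stop_oh(sprintf("row %d: empty patient identifier", i),
              "oh_integrity_error")
    }
    records[[i]] <- new_record(pid, schema$schema_id, cells)
  }
  ids <- vapply(records, `[[`, "", "patient_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop_oh(sprintf("duplicate patient identifiers: %s",
                    paste(dup, collapse = ", ")), "oh_integrity_error")
  }
  attr(records, "parse_notes") <- if (length(notes) > 0L) {
    do.call(rbind, notes)
  } else {
    data.frame(row = integer(), column = character(), raw = character(),
               note = character(), stringsAsFactors = FALSE)
  }
  records
}

#' Write patient records as a REDCap-import-style CSV
#'
#' Header is the schema's variable order; cells are serialized from their raw
#' form, so `parse_export(write_import_csv(records))` reproduces the records
#' field-for-field and a write-read-write cycle is byte-identical.
#'
#' @param records list of `oh_record` sharing one schema.
#' @param schema the governing `oh_schema`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_import_csv <- function(records, schema, path) {
  stopifnot(inherits(schema, "oh_schema"))
  sids <- unique(vapply(records, `[[`, "", "schema_id"))
  if (length(records) > 0L && !identical(sids, schema$schema_id)) {
    stop_oh(sprintf("records span schemas (%s); expected only '%s'",
                    paste(sids, collapse = ", "), schema$schema_id),
            "oh_integrity_error")
  }
  vars <- schema_variable_names(schema)
  esc <- function(x) {
    needs <- grepl('[",\n]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  lines <- paste(esc(vars), collapse = ",")
  id_var <- identifier_variable(schema)
  for (rec in records) {
    row <- vapply(vars, function(var) {
      if (identical(var, id_var)) return(rec$patient_id)
      cell <- rec$cells[[var]]
      if (is.null(cell)) "" else format_cell(cell)
    }, "")
    lines <- c(lines, paste(esc(row), collapse = ","))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
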