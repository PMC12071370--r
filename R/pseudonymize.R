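# Deidentification transforms: double-hashed patient identifiers and
# interval-to-epoch pseudo-date recoding.
#
# Exact calendar dates are indirect identifiers and are never collected;
# capture forms collect durations (a value plus a unit). Where a FHIR element
# nevertheless demands calendar dates, the duration is re-expressed as an
# arbitrary period anchored at 1970-01-01 (mimicking the Unix epoch), whose
# span realizes the collected interval.

EPOCH_DATE <- as.Date("1970-01-01")
INTERVAL_UNITS <- c("days", "weeks", "months")

#' Construct a deidentified time interval
#'
#' @param value non-negative integer number of units.
#' @param unit one of `"days"`, `"weeks"`, `"months"`.
#' @return object of class `oh_interval`.
#' @export
time_interval <- function(value, unit) {
  unit <- match.arg(unit, INTERVAL_UNITS)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value != floor(value)) {
    stop_oh("interval value must be a single non-negative integer",
            "oh_interval_error")
  }
  structure(list(value = as.numeric(value), unit = unit),
            class = "oh_interval")
}

#' @export
format.oh_interval <- function(x, ...) sprintf("%d %s", as.integer(x$value),
                                               x$unit)

#' @export
print.oh_interval <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Double-hash a local patient identifier
#'
#' Two chained keyed SHA-256 stages: the first with the data provider's site
#' salt (applied before any data leaves the site), the second with the
#' platform salt. Each stage hashes `salt || input` and passes on the
#' lowercase hex digest, so the platform never needs the local identifier in
#' clear once stage one has run.
#'
#' @param local_id non-empty local patient identifier.
#' @param site_salt data provider's salt (stage 1).
#' @param platform_salt platform salt (stage 2).
#' @return 64-character lowercase hex digest (the platform patient ID).
#' @export
#' @examples
#' hash_patient_id("PAT001", "siteA", "plat")
hash_patient_id <- function(local_id, site_salt, platform_salt) {
  if (!is_string(local_id) || !nzchar(local_id)) {
    stop_oh("local_id must be a non-empty string", "oh_pseudonym_error")
  }
  stopifnot(is_string(site_salt), is_string(platform_salt))
  stage1 <- digest::digest(paste0(site_salt, local_id), algo = "sha256",
                           serialize = FALSE)
  digest::digest(paste0(platform_salt, stage1), algo = "sha256",
                 serialize = FALSE)
}

#' Recode a time interval into an epoch-anchored pseudo-period
#'
#' The period always starts 1970-01-01; the end date is the start advanced by
#' the interval. Days and weeks (7 days) are exact day arithmetic; months are
#' calendar-month addition, which is unambiguous here because the start is
#' always the first of the month.
#'
#' @param interval an [time_interval()].
#' @return object of class `oh_period`: list(start, end) of `Date`.
#' @export
#' @examples
#' recode_interval(time_interval(4, "months"))  # 1970-01-01 .. 1970-05-01
recode_interval <- function(interval) {
  stopifnot(inherits(interval, "oh_interval"))
  v <- interval$value
  end <- switch(interval$unit,
    days = EPOCH_DATE + v,
    weeks = EPOCH_DATE + 7 * v,
    months = as.Date(sprintf("%04d-%02d-01", 1970 + v %/% 12, 1 + v %% 12))
  )
  structure(list(start = EPOCH_DATE, end = end), class = "oh_period")
}

#' @export
format.oh_period <- function(x, ...) sprintf("%s/%s", format(x$start),
                                             format(x$end))

#' @export
print.oh_period <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Recover the time interval encoded by a pseudo-period
#'
#' Inverse of [recode_interval()] for exactly representable intervals; a
#' period whose span is not a whole number of the requested unit, or which
#' does not start at the epoch date, is an error.
#'
#' @param period an `oh_period` starting 1970-01-01.
#' @param unit requested unit.
#' @return an [time_interval()].
#' @export
decode_period <- function(period, unit) {
  stopifnot(inherits(period, "oh_period"))
  unit <- match.arg(unit, INTERVAL_UNITS)
  if (!identical(as.numeric(period$start), as.numeric(EPOCH_DATE))) {
    stop_oh(sprintf("period does not start at the epoch date: %s",
                    format(period$start)), "oh_pseudonym_error")
  }
  days <- as.numeric(period$end - period$start)
  if (days < 0) {
    stop_oh("period ends before it starts", "oh_pseudonym_error")
  }
  value <- switch(unit,
    days = days,
    weeks = {
      if (days %% 7 != 0) {
        stop_oh(sprintf("%d days is not a whole number of weeks", days),
                "oh_pseudonym_error")
      }
      days / 7
    },
    months = {
      lt <- as.POSIXlt(period$end)
      if (lt$mday != 1L) {
        stop_oh(sprintf(
          "%s is not a calendar-month boundary from the epoch",
          format(period$end)), "oh_pseudonym_error")
      }
      (lt$year + 1900 - 1970) * 12 + lt$mon
    }
  )
  time_interval(value, unit)
}
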