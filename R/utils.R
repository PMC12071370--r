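# Small shared helpers.

#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero for positive
#' numbers (commercial rounding), as used for all displayed quality scores.
#' Base [round()] rounds half-to-even, which would print 0.125 as 0.12.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Deterministic UUID version-4 factory
#'
#' Returns a zero-argument function producing RFC 4122 version-4 UUID strings.
#' With `seed = NULL` the factory draws from R's global random stream; with an
#' integer seed it uses a private stream so that whole-cohort transforms are
#' byte-reproducible without disturbing the caller's RNG state.
#'
#' @param seed optional integer seed for a private, reproducible stream.
#' @return function() -> character(1) UUID.
#' @export
make_id_factory <- function(seed = NULL) {
  rng_state <- NULL
  if (!is.null(seed)) {
    old <- get_rng_state()
    set.seed(as.integer(seed))
    rng_state <- get_rng_state()
    restore_rng_state(old)
  }
  function() {
    if (!is.null(rng_state)) {
      old <- get_rng_state()
      restore_rng_state(rng_state)
      on.exit({
        rng_state <<- get_rng_state()
        restore_rng_state(old)
      })
    }
    bytes <- sample.int(256L, 16L, replace = TRUE) - 1L
    bytes[7] <- bitwOr(bitwAnd(bytes[7], 0x0FL), 0x40L)  # version 4
    bytes[9] <- bitwOr(bitwAnd(bytes[9], 0x3FL), 0x80L)  # RFC 4122 variant
    hex <- sprintf("%02x", bytes)
    paste0(
      paste(hex[1:4], collapse = ""), "-",
      paste(hex[5:6], collapse = ""), "-",
      paste(hex[7:8], collapse = ""), "-",
      paste(hex[9:10], collapse = ""), "-",
      paste(hex[11:16], collapse = "")
    )
  }
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_oh <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "oh_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
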