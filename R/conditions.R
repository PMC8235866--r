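# Classed conditions used across the package. Every user-facing failure is one
# of these four classes so callers (and the CLI) can distinguish bad input
# (exit 1) from internal faults (exit 2).

gx_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "gx_error"), ...)
}

#' @noRd
gx_format_error <- function(message, ...) gx_abort("gx_format_error", message, ...)

#' @noRd
gx_parse_error <- function(message, ...) gx_abort("gx_parse_error", message, ...)

#' @noRd
gx_integrity_error <- function(message, ...) gx_abort("gx_integrity_error", message, ...)

#' @noRd
gx_validation_error <- function(message, ...) gx_abort("gx_validation_error", message, ...)

#' @noRd
gx_reference_error <- function(message, ...) gx_abort("gx_reference_error", message, ...)

#' @noRd
gx_io_error <- function(message, ...) gx_abort("gx_io_error", message, ...)

gx_warn <- function(message, class = "gx_validation_warning") {
  rlang::warn(message, class = class)
}

# match.arg with a classed validation error instead of a base error
gx_match_arg <- function(arg, choices, what) {
  if (length(arg) != 1L || !arg %in% choices) {
    gx_validation_error(sprintf(
      "%s must be one of %s, got %s", what,
      paste(sQuote(choices), collapse = ", "),
      sQuote(paste(as.character(arg), collapse = ","))
    ))
  }
  arg
}
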