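#' @title Error conditions
#' @description
#' All package errors are classed conditions so callers (and the audit
#' harness) can distinguish a rejected input from a genuine crash. Every
#' condition inherits from `minichi_error`; parse failures additionally carry
#' a short `code` naming the violated rule ("prefix", "layer-order",
#' "connections", "element", "count", "paren", "dup-bond", "range", "mobile",
#' "parity", ...).
#' @name minichi-conditions
#' @keywords internal
NULL

stop_minichi <- function(class, code, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "minichi_error", "error", "condition"),
    list(message = sprintf("[%s] %s", code, msg), code = code, call = NULL)
  )
  stop(cond)
}

parse_error       <- function(code, msg) stop_minichi("minichi_parse_error", code, msg)
serialize_error   <- function(code, msg) stop_minichi("minichi_serialize_error", code, msg)
format_error      <- function(code, msg) stop_minichi("minichi_format_error", code, msg)
reconstruct_error <- function(code, msg) stop_minichi("minichi_reconstruct_error", code, msg)
argument_error    <- function(code, msg) stop_minichi("minichi_argument_error", code, msg)
generate_error    <- function(code, msg) stop_minichi("minichi_generate_error", code, msg)
perception_error  <- function(code, msg) stop_minichi("minichi_perception_error", code, msg)
instability_error <- function(code, msg) stop_minichi("minichi_instability_error", code, msg)

#' Condition code of a caught minichi error
#'
#' @param cond a condition object signalled by this package.
#' @return the short machine-readable code, or `NA_character_`.
#' @export
error_code <- function(cond) {
  if (!is.null(cond$code)) cond$code else NA_character_
}
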