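# Internal condition helpers. Every user-facing error carries a subclass so
# callers (and tests) can distinguish schema problems from validation,
# configuration, alignment and numerical failures.

ct_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "ct_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ct_schema_error     <- function(msg, ...) ct_error("ct_schema_error", msg, ...)
ct_validation_error <- function(msg, ...) ct_error("ct_validation_error", msg, ...)
ct_config_error     <- function(msg, ...) ct_error("ct_config_error", msg, ...)
ct_alignment_error  <- function(msg, ...) ct_error("ct_alignment_error", msg, ...)
ct_numeric_error    <- function(msg, ...) ct_error("ct_numeric_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
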