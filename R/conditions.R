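#' @keywords internal
#' Signal an input/validation error (maps to exit code 2 in the CLI).
input_error <- function(msg, ...) {
  stop(structure(
    class = c("lrescan_input_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_input_error <- function(e) inherits(e, "lrescan_input_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
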