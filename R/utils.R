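#' @importFrom rlang abort warn %||%
#' @keywords internal
abort_ddmqa <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "ddmqa_error"), ...)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# round a length up to a decimal step, tolerating float fuzz
# (e.g. 0.2 mm stays 0.2 mm, not 0.3)
ceiling_to <- function(x, step) {
  ceiling(x / step - 1e-9) * step
}
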