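# Internal helpers shared across the package.

# Classed conditions so callers (and tests) can distinguish validation
# failures from parse failures and plain I/O errors.
oq_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "orthoquant_error", "error"),
                      call = call))
}

oq_validation_error <- function(msg) oq_abort(msg, "orthoquant_validation_error")
oq_parse_error <- function(msg) oq_abort(msg, "orthoquant_parse_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero; base round() goes to even, which disagrees
# with the reporting convention used for "~N%" overlap figures.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
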