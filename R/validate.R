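#' @keywords internal
"_PACKAGE"

# Signal a user/validation error. These carry class "biofilmq_validation_error"
# so the command-line layer can map them to exit code 2, while genuine internal
# failures keep exit code 1.
abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("biofilmq_validation_error", "error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_scalar_number(x)) {
    abort_validation("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    abort_validation("'%s' must be in [%s, %s], got %s", name,
                     format(lower), format(upper), format(x))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_scalar(x, name, lower = lower)
  if (x != round(x)) abort_validation("'%s' must be an integer", name)
  invisible(as.integer(x))
}
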