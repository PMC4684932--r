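# Classed conditions so callers (and the CLI) can map error kinds to exit codes.

np_stop <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "np_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

np_invalid_parameter <- function(message) np_stop(message, "np_invalid_parameter")
np_usage_error       <- function(message) np_stop(message, "np_usage_error")
np_validation_error  <- function(message) np_stop(message, "np_validation_error")
np_io_error          <- function(message) np_stop(message, "np_io_error")

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    np_invalid_parameter(sprintf("`%s` must be a single finite number", name))
  as.numeric(x)
}

check_count <- function(x, name, min = 1L) {
  x <- check_scalar(x, name)
  if (x != round(x) || x < min)
    np_invalid_parameter(sprintf("`%s` must be an integer >= %d", name, min))
  as.integer(x)
}
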