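# Classed conditions so callers and tests can distinguish failure modes.

gcs_stop <- function(class, fmt, ...) {
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "gcs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  ))
}

gcs_warn <- function(class, fmt, ...) {
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  warning(structure(
    class = c(class, "gcs_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1L))
  ))
}
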