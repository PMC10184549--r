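# classed error conditions so callers and tests can discriminate failures

abort_cavex <- function(message, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "cavex_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

warn_cavex <- function(message, class, ...) {
  warning(structure(
    class = c(class, "cavex_warning", "warning", "condition"),
    list(message = message, call = NULL, ...)
  ))
}
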