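# Classed conditions so callers (and the CLI) can map failure modes to
# exit codes: format/uniqueness errors -> 2, configuration errors -> 3.

stop_format <- function(msg, ...) {
  stop(structure(
    class = c("derepool_format_error", "derepool_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_unique <- function(msg, ...) {
  stop(structure(
    class = c("derepool_uniqueness_error", "derepool_format_error",
              "derepool_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_config <- function(msg, ...) {
  stop(structure(
    class = c("derepool_config_error", "derepool_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_consistency <- function(msg, ...) {
  stop(structure(
    class = c("derepool_consistency_error", "derepool_error", "error",
              "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
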