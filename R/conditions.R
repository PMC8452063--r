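# Coded error conditions. Every user-facing failure mode raises a classed
# condition so callers (and tests) can branch on the class rather than on
# message text.

gmte_abort <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("gmte_error_", class), "gmte_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

gmte_warn <- function(msg, class) {
  warning(structure(
    class = c(paste0("gmte_warning_", class), "gmte_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
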