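# Classed conditions so callers can distinguish recoverable per-tree failures
# (rooting, mapping, group cap) from genuine usage errors.

mr_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mulrec_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  ))
}

mr_assert <- function(cond, class, message) {
  if (!isTRUE(cond)) mr_error(class, message)
  invisible(TRUE)
}
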