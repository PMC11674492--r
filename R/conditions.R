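# Classed error helper: every user-facing failure mode raises a condition whose
# class identifies it (all inherit from "cyclicity_error"), so callers can
# distinguish e.g. a duplicate-label header from a ragged row programmatically.
stop_ca <- function(class, msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(errorCondition(msg, class = c(class, "cyclicity_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
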