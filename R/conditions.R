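# Classed conditions so callers can distinguish, e.g., a vocabulary rejection
# from a registry lookup failure. Every error also carries class
# "clonetrack_error".

ct_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "clonetrack_error")))
}

ct_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "clonetrack_warning")))
}
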