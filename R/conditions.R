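# Typed condition helpers. Every user-facing failure raises a condition whose
# class carries the failure kind so callers (and the fuzz tests) can branch on
# it instead of matching message text.

ojip_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "ojip_error"), call = call))
}

ojip_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "ojip_warning")))
}
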