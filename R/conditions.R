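# Internal condition helpers: every user-facing failure is a classed condition
# so callers (and tests) can discriminate error kinds.

pw_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "protonWET_error"),
                      call = call))
}

pw_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "protonWET_warning")))
}

pw_check <- function(ok, message, class = "protonWET_validation_error") {
  if (!isTRUE(ok)) pw_abort(message, class, call = sys.call(-1))
  invisible(TRUE)
}
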