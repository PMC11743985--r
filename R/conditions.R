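# Classed error/warning helpers so callers can branch on failure modes
# rather than matching message strings.

abort_painattn <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "painattn_error"),
                      call = call))
}

warn_painattn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "painattn_warning")))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_painattn(sprintf("`%s` must be a single finite number", name),
                   "invalid_config")
  if (positive && x <= 0)
    abort_painattn(sprintf("`%s` must be > 0", name), "invalid_config")
  invisible(x)
}
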