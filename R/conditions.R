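# Classed conditions so callers and tests can distinguish failure modes.

stop_tm <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("trackmsd_", class), "trackmsd_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

warn_tm <- function(msg, class) {
  warning(structure(
    class = c(paste0("trackmsd_", class), "trackmsd_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# scalar checks used across constructors
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive_scalar <- function(x, name) {
  if (!is_scalar_num(x) || x <= 0)
    stop_tm(sprintf("`%s` must be a single positive finite number", name),
            "input_error")
  invisible(x)
}
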