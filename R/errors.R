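# Condition helpers: every user-facing failure carries a class so callers
# (and the CLI) can distinguish format, integrity, mapping, parameter and
# usage problems programmatically.

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = "npx_format_error", ...)
}

abort_integrity <- function(msg, ...) {
  rlang::abort(msg, class = "npx_integrity_error", ...)
}

abort_mapping <- function(msg, ...) {
  rlang::abort(msg, class = "npx_mapping_error", ...)
}

abort_parameter <- function(msg, ...) {
  rlang::abort(msg, class = "npx_parameter_error", ...)
}

abort_usage <- function(msg, ...) {
  rlang::abort(msg, class = "npx_usage_error", ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = "npx_degenerate_error", ...)
}
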