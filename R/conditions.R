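# Classed conditions used across the package so callers can distinguish
# configuration mistakes from topology, data and solver failures.

abort_earmech <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "earmech_error")))
}

abort_config <- function(msg) abort_earmech(msg, "earmech_config_error")
abort_topology <- function(msg) abort_earmech(msg, "earmech_topology_error")
abort_domain <- function(msg) abort_earmech(msg, "earmech_domain_error")
abort_data <- function(msg) abort_earmech(msg, "earmech_data_error")
abort_solver <- function(msg) abort_earmech(msg, "earmech_solver_error")
abort_format <- function(msg) abort_earmech(msg, "earmech_format_error")

warn_earmech <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "earmech_warning")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}
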