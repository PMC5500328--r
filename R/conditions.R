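# Classed error conditions so callers (and the CLI) can react to failure
# categories rather than matching message strings.

st_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c(class, "slidetiler_error", "error")))
}

st_not_found          <- function(fmt, ...) st_stop("st_not_found", fmt, ...)
st_unsupported_format <- function(fmt, ...) st_stop("st_unsupported_format", fmt, ...)
st_series_error       <- function(fmt, ...) st_stop("st_series_error", fmt, ...)
st_bounds_error       <- function(fmt, ...) st_stop("st_bounds_error", fmt, ...)
st_parameter_error    <- function(fmt, ...) st_stop("st_parameter_error", fmt, ...)
st_parse_error        <- function(fmt, ...) st_stop("st_parse_error", fmt, ...)
st_missing_key        <- function(fmt, ...) st_stop("st_missing_key", fmt, ...)
st_no_data            <- function(fmt, ...) st_stop("st_no_data", fmt, ...)
st_load_error         <- function(fmt, ...) st_stop("st_load_error", fmt, ...)
st_config_error       <- function(fmt, ...) st_stop("st_config_error", fmt, ...)
st_io_error           <- function(fmt, ...) st_stop("st_io_error", fmt, ...)
st_placement_error    <- function(fmt, ...) st_stop("st_placement_error", fmt, ...)
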